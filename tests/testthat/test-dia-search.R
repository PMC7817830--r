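# Shared small simulated runs (built once; tests only read them)
planted_sim <- simulate_dia(sim_config(seed = 21))
null_sim <- simulate_dia(sim_config(seed = 22, sites = integer()))

test_that("extract_xic isolates planted peaks per cycle", {
  run <- planted_sim$run
  p <- planted_sim$manifest$planted[[1]]
  xic <- extract_xic(run, p$precursor_mz, 15, window = NULL)
  expect_equal(nrow(xic), length(unique(run$cycle)))
  # apex within one cycle period of the planted elution apex
  apex <- xic$rt_s[which.max(xic$intensity)]
  expect_lte(abs(apex - p$apex_rt), sim_config()$cycle_period)
  # single planted peak, zero tolerance: only the exact m/z contributes
  sch1 <- swath_scheme(600, 50, 650)
  path_run <- as_spectrum_run(dplyr::bind_rows(
    tibble::tibble(cycle = 1:2, ms_level = 1L, rt_s = c(0, 2),
                   window_id = NA_integer_, window_low = NA_real_,
                   window_high = NA_real_,
                   mz = list(c(700.0), c(700.5)), intensity = list(5, 7)),
    tibble::tibble(cycle = 1:2, ms_level = 2L, rt_s = c(0.5, 2.5),
                   window_id = 1L, window_low = 600, window_high = 650,
                   mz = list(numeric(), numeric()),
                   intensity = list(numeric(), numeric()))),
    sch1)
  tr0 <- extract_xic(path_run, 700.0, 0)
  expect_equal(tr0$intensity, c(5, 0))
})

test_that("diagnostic screening finds the planted window and nothing on null", {
  d <- diagnostic_ion_set()
  cands <- screen_diagnostics(planted_sim$run, d)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$window_id, planted_sim$manifest$planted[[1]]$window_id)
  expect_lte(abs(cands$apex_rt - planted_sim$manifest$planted[[1]]$apex_rt),
             2 * sim_config()$cycle_period)
  expect_gte(cands$co_detected, 5)
  # null run: nothing co-elutes
  expect_equal(nrow(screen_diagnostics(null_sim$run, d)), 0)
})

test_that("a single planted diagnostic peak is found at k = 1", {
  sch <- swath_scheme()
  d1 <- diagnostic_ion_set()[1, ]
  rows <- list()
  for (cy in 1:3) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      cycle = cy, ms_level = 1L, rt_s = cy * 2, window_id = NA_integer_,
      window_low = NA_real_, window_high = NA_real_,
      mz = list(numeric()), intensity = list(numeric()))
    for (w in sch$window_id) {
      planted <- w == 3 && cy == 2
      rows[[length(rows) + 1]] <- tibble::tibble(
        cycle = cy, ms_level = 2L, rt_s = cy * 2 + w * 0.01, window_id = w,
        window_low = sch$low[w], window_high = sch$high[w],
        mz = list(if (planted) d1$mz else numeric()),
        intensity = list(if (planted) 100 else numeric()))
    }
  }
  run <- as_spectrum_run(dplyr::bind_rows(rows), sch)
  cands <- screen_diagnostics(run, d1, min_codetected = 1)
  expect_equal(cands$window_id, 3L)
})

test_that("precursor matching deconvolutes charge and ranks by ppm", {
  p <- planted_sim$manifest$planted[[1]]
  db <- enumerate_conjugates(digest(fixture_proteins()$sequence[1], 2))
  cand <- tibble::tibble(window_id = p$window_id, apex_rt = p$apex_rt)
  hyps <- match_precursor(cand, db, planted_sim$run)
  expect_gte(nrow(hyps), 1)
  expect_equal(hyps$backbone[1], "IISKIENHEGVR")
  expect_equal(hyps$charge[1], 3L)
  expect_lte(abs(hyps$ppm_error[1]), 15)
  # conjugate database without the matching mass: no hit, flagged distinctly
  db_off <- db
  db_off$neutral_mass <- db_off$neutral_mass + 100
  miss <- match_precursor(cand, db_off, planted_sim$run)
  expect_equal(nrow(miss), 0)
  expect_equal(attr(miss, "status"), "no_match")
  # no MS1 peak in the window at that time: distinct flag
  quiet <- simulate_dia(sim_config(seed = 30, sites = integer(),
                                   noise_density = 0))
  none <- match_precursor(cand, db, quiet$run)
  expect_equal(attr(none, "status"), "no_ms1_peak")
  # two database entries within tolerance are both returned, best first
  db2 <- tibble::tibble(
    backbone = c("near", "nearer"),
    neutral_mass = conjugate_mass(p$conjugate) * c(1 + 5e-6, 1),
    conjugate = list(p$conjugate, p$conjugate))
  both <- match_precursor(cand, db2, planted_sim$run)
  expect_equal(nrow(both), 2)
  expect_equal(both$backbone[1], "nearer")
  expect_true(abs(both$ppm_error[1]) <= abs(both$ppm_error[2]))
})

test_that("fragment mapping scores self-matches at 1 and noise below floor", {
  bc <- k270_conjugate()
  theo <- fragment_conjugate(bc, max_charge = 2)
  rec <- map_fragments(bc, theo$mz, rep(1, nrow(theo)))
  expect_equal(rec$matched_fraction, 1)
  expect_equal(rec$intensity_fraction, 1)
  expect_true(rec$accepted)
  expect_equal(rec$annotation,
               "K270 conjugated with ELGMEEEDVIEVYQEQTGG remnant")
  set.seed(33)
  noise_mz <- runif(60, 100, 2000)
  rec_n <- map_fragments(bc, noise_mz, rep(1, 60))
  expect_lt(rec_n$matched_fraction, 0.3)
  expect_false(rec_n$accepted)
  expect_error(map_fragments(bc, numeric(), numeric()), "empty")
})

test_that("the three stages recover the planted site end to end", {
  ids <- search_dia(planted_sim$run, fixture_proteins()[1, ])
  expect_equal(nrow(ids), 1)
  expect_equal(ids$protein_site, 9L)
  expect_equal(ids$backbone, "IISKIENHEGVR")
  expect_equal(ids$annotation,
               "K9 conjugated with ELGMEEEDVIEVYQEQTGG remnant")
  expect_gt(ids$matched_fraction, 0.9)
  fun <- glance(ids)
  expect_equal(fun$n_records, 1)
  expect_gte(fun$n_candidates, 1)
  # null run produces no accepted records
  ids0 <- search_dia(null_sim$run, fixture_proteins()[1, ])
  expect_equal(nrow(ids0), 0)
})

test_that("raising thresholds never increases reported records", {
  base <- nrow(search_dia(planted_sim$run, fixture_proteins()[1, ],
                          settings = dia_settings()))
  stricter_k <- nrow(search_dia(planted_sim$run, fixture_proteins()[1, ],
                                settings = dia_settings(min_codetected = 15)))
  stricter_floor <- nrow(search_dia(planted_sim$run, fixture_proteins()[1, ],
                                    settings = dia_settings(score_floor = 0.99)))
  expect_lte(stricter_k, base)
  expect_lte(stricter_floor, base)
})

test_that("diagnostic traces never exceed their window's total intensity", {
  run <- planted_sim$run
  d <- diagnostic_ion_set()
  w <- planted_sim$manifest$planted[[1]]$window_id
  total <- sum(unlist(run$intensity[run$ms_level == 2 &
                                      !is.na(run$window_id) &
                                      run$window_id == w]))
  xic_sum <- sum(vapply(d$mz, function(mz)
    sum(extract_xic(run, mz, 25, window = w)$intensity), double(1)))
  expect_lte(xic_sum, total + 1e-9)
})
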