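test_that("explicit product selection reproduces the printed transitions", {
  tr <- k270_transitions()
  light <- tr$product_mz[tr$isotope == "light"]
  heavy <- tr$product_mz[tr$isotope == "heavy"]
  expect_true(all(abs(round_half_up(light, 2) -
                        c(754.92, 805.44, 933.99, 860.08)) <= 0.01 + 1e-9))
  expect_equal(round_half_up(heavy, 2), c(757.92, 808.44, 936.99, 862.42))
  # stored m/z recomputable from the fragment table to high precision
  hl <- k270_heavy_labels()
  bch <- branched_conjugate("IISKIENHEGVR", 4, protein_site = 270,
                            backbone_labels = hl$backbone,
                            branch_labels = hl$branch)
  frh <- fragment_conjugate(bch, max_charge = 3)
  for (i in which(tr$isotope == "heavy")) {
    ref <- frh$mz[frh$series == tr$product_series[i] &
                    frh$index == tr$product_index[i] &
                    frh$charge == tr$product_z[i]]
    expect_lt(abs(ref - tr$product_mz[i]), 1e-6)
  }
})

test_that("heavy minus light equals contained label shifts over charge", {
  tr <- k270_transitions()
  dL <- isotope_shift("L")   # remnant Leu, rides with the backbone-b4 ion
  dV <- isotope_shift("V")   # backbone Val, rides with every branch-y' ion
  for (i in which(tr$isotope == "light")) {
    j <- which(tr$isotope == "heavy" &
                 tr$product_series == tr$product_series[i] &
                 tr$product_index == tr$product_index[i] &
                 tr$product_z == tr$product_z[i])
    expected <- if (tr$product_series[i] == "branch-y'") dV else dL
    expect_equal(tr$product_mz[j] - tr$product_mz[i],
                 expected / tr$product_z[i], tolerance = 1e-12)
  }
})

test_that("ranking uses the reference spectrum and warns when short", {
  bc <- k270_conjugate()
  cand <- fragment_conjugate(bc, max_charge = 2)
  # reference spectrum with a unique maximum at one product
  target <- cand[cand$series == "branch-b" & cand$index == 3 &
                   cand$charge == 1, ]
  ref <- list(mz = c(target$mz, 500.0), intensity = c(100, 1))
  tr1 <- design_transitions(bc, n = 1, reference = ref,
                            product_charges = 1:2)
  expect_equal(tr1$product_series, "branch-b")
  expect_equal(tr1$product_index, 3L)
  # requesting more products than exist returns all, with a warning
  small <- branched_conjugate("AKA", 2, branch = "GG")
  expect_warning(design_transitions(small, n = 500, product_charges = 1),
                 "candidate")
  expect_error(design_transitions(bc, n = 0), "n must be")
})

test_that("peak integration handles triangles, flats and Gaussians", {
  tri <- list(time = c(0, 1, 2), intensity = c(0, 1, 0))
  pk <- integrate_peak(tri)
  expect_equal(pk$area, 1.0)
  expect_equal(pk$apex_rt, 1)
  expect_equal(pk$flag, "ok")
  flat <- list(time = 0:5, intensity = rep(0, 6))
  pk0 <- integrate_peak(flat)
  expect_equal(pk0$area, 0)
  expect_equal(pk0$flag, "no_peak")
  # noise-free Gaussian, amplitude A and width sigma
  A <- 50; sigma <- 3
  t <- seq(0, 60, by = 0.1)
  y <- A * exp(-(t - 30)^2 / (2 * sigma^2))
  full <- A * sigma * sqrt(2 * pi)
  # default 5%-of-apex boundaries truncate the peak: compare against the
  # truncated, baseline-subtracted closed form
  pk5 <- integrate_peak(list(time = t, intensity = y))
  half_width <- sigma * sqrt(-2 * log(0.05))
  truncated <- full * (stats::pnorm(half_width / sigma) -
                         stats::pnorm(-half_width / sigma)) -
    0.05 * A * 2 * half_width
  expect_equal(pk5$area, truncated, tolerance = 0.02)
  # with a near-zero boundary fraction the full closed form is recovered
  pk0f <- integrate_peak(list(time = t, intensity = y),
                         boundary_frac = 0.005)
  expect_equal(pk0f$area, full, tolerance = 0.02)
  # boundaries bracket the apex inside the trace span
  expect_true(pk5$left <= pk5$apex_rt && pk5$apex_rt <= pk5$right)
  expect_true(pk5$left >= min(t) && pk5$right <= max(t))
})

test_that("area scales linearly with intensity", {
  set.seed(7)
  t <- seq(0, 40, by = 0.5)
  y <- 20 * exp(-(t - 20)^2 / 8) + runif(length(t), 0, 0.1)
  a1 <- integrate_peak(list(time = t, intensity = y))$area
  a3 <- integrate_peak(list(time = t, intensity = 3 * y))$area
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
})

test_that("quantification recovers ratios and flags degenerate cases", {
  tr <- k270_transitions()
  sim <- simulate_mrm(mrm_sim_config(seed = 13), tr, ratio = 0.5)
  q <- quantify_run(sim$chromatograms, tr)
  expect_equal(q$samples$ratio, 0.5, tolerance = 0.05)
  expect_equal(q$samples$ratio_flag, "ok")
  # doubling all light traces doubles the light sum and the ratio exactly
  ch2 <- sim$chromatograms
  light_ids <- tr$transition_id[tr$isotope == "light"]
  for (i in which(ch2$transition_id %in% light_ids)) {
    ch2$intensity[[i]] <- 2 * ch2$intensity[[i]]
  }
  q2 <- quantify_run(ch2, tr)
  expect_equal(q2$samples$light_area, 2 * q$samples$light_area,
               tolerance = 1e-12)
  expect_equal(q2$samples$heavy_area, q$samples$heavy_area)
  expect_equal(q2$samples$ratio, 2 * q$samples$ratio, tolerance = 1e-12)
  # zero planted light signal: ratio ~ 0, all areas finite
  sim0 <- simulate_mrm(mrm_sim_config(seed = 14, noise_frac = 0), tr, 0)
  q0 <- quantify_run(sim0$chromatograms, tr)
  expect_equal(q0$samples$ratio, 0)
  expect_true(all(is.finite(q0$samples$light_area)))
  # all-zero heavy traces: undefined ratio is flagged
  ch0 <- sim0$chromatograms
  for (i in seq_len(nrow(ch0))) ch0$intensity[[i]] <- 0 * ch0$intensity[[i]]
  qh <- quantify_run(ch0, tr)
  expect_equal(qh$samples$ratio_flag, "undefined_ratio")
  expect_true(is.na(qh$samples$ratio))
  # missing chromatogram for a designed transition is an error
  expect_error(quantify_run(sim$chromatograms[-1, ], tr), "no chromatogram")
})

test_that("tidy and glance expose areas and a run summary", {
  tr <- k270_transitions()
  sim <- simulate_mrm(mrm_sim_config(seed = 15), tr, ratio = 1)
  q <- quantify_run(sim$chromatograms, tr)
  td <- tidy(q)
  expect_equal(nrow(td), 8)
  expect_true(all(td$area >= 0))
  gl <- glance(q)
  expect_equal(gl$n_runs, 1)
  expect_equal(gl$median_ratio, 1, tolerance = 0.05)
})
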