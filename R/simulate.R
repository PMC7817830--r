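# Seeded generators for DIA runs and MRM chromatograms with planted
# branched-peptide signals and a ground-truth manifest. All randomness is
# drawn inside a locally scoped RNG so callers' RNG state is untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic substrate proteins for testing
#'
#' A minimal synthetic protein that embeds the K270-containing tryptic
#' backbone IISKIENHEGVR between tryptic boundaries (the conjugatable
#' lysine sits at protein position 9), plus a K-to-R variant carrying no
#' conjugatable lysine. These are synthetic constructs, not fragments of
#' any database protein.
#'
#' @return A tibble with columns `id`, `sequence`, `site` (NA for the
#'   variant).
#' @export
fixture_proteins <- function() {
  tibble::tibble(
    id = c("SYN_SUMO_SUBSTRATE", "SYN_SUMO_SUBSTRATE_KR"),
    sequence = c("MFEGRIISKIENHEGVRAAELR", "MFEGRIISRIENHEGVRAAELR"),
    site = c(9L, NA_integer_))
}

#' Simulation settings for a synthetic DIA run
#'
#' Defaults emulate the modeled acquisition: 25-amu isolation windows over
#' m/z 600-1250, a cycled MS1 + per-window MS2 scan sequence, Gaussian
#' elution of the planted conjugate, uniform-m/z noise peaks with
#' log-uniform intensities, and per-peak m/z jitter.
#'
#' @param protein,protein_id Substrate sequence and identifier.
#' @param sites Protein residue numbers of planted conjugated lysines;
#'   empty integer for a null (noise-only) run.
#' @param remnant Remnant sequence attached at each planted site.
#' @param abundance Apex intensity of the planted precursor.
#' @param precursor_charge Planted precursor charge state.
#' @param apex_rt,sigma_rt Gaussian elution apex and width (s).
#' @param cycle_period,duration Acquisition cycle period and run length (s).
#' @param noise_density Noise peaks per spectrum.
#' @param noise_floor Lower bound of noise intensities.
#' @param noise_ceiling_frac Upper bound as a fraction of `abundance`.
#' @param mz_jitter_ppm Per-peak m/z jitter (ppm, uniform).
#' @param scheme_start,scheme_width,scheme_end Isolation-window scheme.
#' @param ms2_mz_range m/z range of MS2 noise peaks.
#' @param fragment_max_charge Planted fragment charges (1..this).
#' @param missed_cleavages Digest depth used to derive the planted
#'   conjugate backbone.
#' @param seed RNG seed; identical seed and settings give byte-identical
#'   output.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(protein = fixture_proteins()$sequence[1],
                       protein_id = fixture_proteins()$id[1],
                       sites = 9L,
                       remnant = sumo1_remnant(),
                       abundance = 1000,
                       precursor_charge = 3,
                       apex_rt = 40, sigma_rt = 5,
                       cycle_period = 2, duration = 80,
                       noise_density = 50, noise_floor = 1,
                       noise_ceiling_frac = 0.5,
                       mz_jitter_ppm = 5,
                       scheme_start = 600, scheme_width = 25,
                       scheme_end = 1250,
                       ms2_mz_range = c(100, 2000),
                       fragment_max_charge = 2,
                       missed_cleavages = 2,
                       seed = 1) {
  cfg <- list(protein = protein, protein_id = protein_id,
              sites = as.integer(sites), remnant = remnant,
              abundance = abundance, precursor_charge = precursor_charge,
              apex_rt = apex_rt, sigma_rt = sigma_rt,
              cycle_period = cycle_period, duration = duration,
              noise_density = noise_density, noise_floor = noise_floor,
              noise_ceiling_frac = noise_ceiling_frac,
              mz_jitter_ppm = mz_jitter_ppm,
              scheme_start = scheme_start, scheme_width = scheme_width,
              scheme_end = scheme_end, ms2_mz_range = ms2_mz_range,
              fragment_max_charge = fragment_max_charge,
              missed_cleavages = missed_cleavages, seed = seed)
  if (cfg$sigma_rt <= 0) abort("sigma_rt must be > 0")
  if (cfg$cycle_period <= 0) abort("cycle_period must be > 0")
  if (cfg$mz_jitter_ppm < 0) abort("mz_jitter_ppm must be >= 0")
  if (cfg$noise_density < 0) abort("noise_density must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

.jitter_mz <- function(mz, ppm) {
  if (ppm == 0 || length(mz) == 0) return(mz)
  mz * (1 + runif(length(mz), -ppm, ppm) * 1e-6)
}

.noise_peaks <- function(n, mz_range, floor, ceiling) {
  if (n == 0) return(list(mz = numeric(), intensity = numeric()))
  list(mz = runif(n, mz_range[1], mz_range[2]),
       intensity = exp(runif(n, log(floor), log(max(ceiling, floor * 1.01)))))
}

#' Simulate a DIA run with planted branched-peptide signals
#'
#' Generates a cycled SWATH acquisition: each cycle holds one MS1 spectrum
#' and one MS2 spectrum per isolation window. Planted conjugates
#' contribute a precursor peak (MS1) and their full theoretical fragment
#' set (MS2, in the precursor's window) with Gaussian-in-time intensities
#' and rank-decaying (1/rank) relative fragment intensities; every
#' spectrum additionally receives noise peaks at uniform m/z with
#' log-uniform intensity. Identical seeds give identical runs.
#'
#' @param config A [sim_config()].
#' @return A list with elements `run` (a `spectrum_run`) and `manifest`
#'   (ground truth: per planted site the conjugate, precursor m/z and
#'   window, apex retention time and fragment table).
#' @export
simulate_dia <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  scheme <- swath_scheme(config$scheme_start, config$scheme_width,
                         config$scheme_end)
  # derive planted conjugates from the digest, as the search itself would
  planted <- list()
  if (length(config$sites) > 0) {
    peps <- digest(config$protein, config$missed_cleavages)
    db <- enumerate_conjugates(peps, config$remnant)
    for (s in config$sites) {
      hit <- db[db$protein_site == s, ]
      if (nrow(hit) == 0) abort(sprintf("no conjugate at site %d", s))
      hit <- hit[which.min(hit$missed_cleavages), ]
      conj <- hit$conjugate[[1]]
      pmz <- conjugate_mz(conj, config$precursor_charge)
      wid <- window_lookup(scheme, pmz)
      if (is.na(wid)) {
        abort(sprintf(
          "planted precursor m/z %.4f lies outside the window scheme", pmz))
      }
      fr <- fragment_conjugate(conj,
                               max_charge = config$fragment_max_charge)
      fr$rel_intensity <- 1 / seq_len(nrow(fr))
      planted[[length(planted) + 1]] <- list(
        conjugate = conj, backbone = hit$backbone, site = s,
        precursor_mz = pmz, precursor_charge = config$precursor_charge,
        window_id = wid, apex_rt = config$apex_rt,
        sigma_rt = config$sigma_rt, fragments = fr)
    }
  }
  ceiling_int <- config$noise_ceiling_frac * config$abundance
  cycle_times <- seq(0, config$duration, by = config$cycle_period)
  nw <- nrow(scheme)
  rows <- list()
  .with_seed(config$seed, {
    for (ci in seq_along(cycle_times)) {
      t <- cycle_times[ci]
      # MS1
      nz <- .noise_peaks(config$noise_density,
                         c(config$scheme_start, config$scheme_end),
                         config$noise_floor, ceiling_int)
      mz <- nz$mz
      int <- nz$intensity
      for (p in planted) {
        h <- config$abundance *
          exp(-(t - p$apex_rt)^2 / (2 * p$sigma_rt^2))
        if (h > 1e-6 * config$abundance) {
          mz <- c(mz, .jitter_mz(p$precursor_mz, config$mz_jitter_ppm))
          int <- c(int, h)
        }
      }
      o <- order(mz)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cycle = ci, ms_level = 1L, rt_s = t, window_id = NA_integer_,
        window_low = NA_real_, window_high = NA_real_,
        mz = list(mz[o]), intensity = list(int[o]))
      # MS2 per window
      for (w in seq_len(nw)) {
        nz <- .noise_peaks(config$noise_density, config$ms2_mz_range,
                           config$noise_floor, ceiling_int)
        mz <- nz$mz
        int <- nz$intensity
        for (p in planted) {
          if (p$window_id != w) next
          h <- config$abundance *
            exp(-(t - p$apex_rt)^2 / (2 * p$sigma_rt^2))
          if (h > 1e-6 * config$abundance) {
            mz <- c(mz, .jitter_mz(p$fragments$mz, config$mz_jitter_ppm))
            int <- c(int, h * p$fragments$rel_intensity)
          }
        }
        o <- order(mz)
        rows[[length(rows) + 1]] <- tibble::tibble(
          cycle = ci, ms_level = 2L,
          rt_s = t + w * config$cycle_period / (nw + 2),
          window_id = w, window_low = scheme$low[w],
          window_high = scheme$high[w],
          mz = list(mz[o]), intensity = list(int[o]))
      }
    }
  })
  run <- as_spectrum_run(dplyr::bind_rows(rows), scheme)
  manifest <- structure(
    list(config = config, planted = planted, scheme = scheme),
    class = "synthetic_run_manifest")
  list(run = run, manifest = manifest)
}

#' Simulation settings for MRM chromatograms
#'
#' @param base_area Total heavy-standard peak area per peptide (summed
#'   over its transitions).
#' @param apex_rt,sigma_rt Gaussian elution apex and width (s).
#' @param duration,sample_period Trace length and sampling interval (s).
#' @param noise_frac Baseline noise ceiling as a fraction of the largest
#'   heavy transition's apex height (uniform noise on every sample).
#' @param seed RNG seed.
#' @return A named list of class `mrm_sim_config`.
#' @export
mrm_sim_config <- function(base_area = 1000, apex_rt = 30, sigma_rt = 3,
                           duration = 60, sample_period = 0.5,
                           noise_frac = 0.002, seed = 1) {
  cfg <- list(base_area = base_area, apex_rt = apex_rt, sigma_rt = sigma_rt,
              duration = duration, sample_period = sample_period,
              noise_frac = noise_frac, seed = seed)
  if (cfg$sigma_rt <= 0) abort("sigma_rt must be > 0")
  class(cfg) <- "mrm_sim_config"
  cfg
}

#' Simulate MRM chromatograms realizing a target light/heavy ratio
#'
#' Heavy transitions of a peptide share `base_area` with 1/rank relative
#' weights; each light transition carries `ratio` times its heavy
#' partner's area. Peaks are Gaussian in time on a uniform baseline-noise
#' floor; a ratio of zero plants no light signal at all.
#'
#' @param config An [mrm_sim_config()].
#' @param transitions A [design_transitions()] table containing light and
#'   heavy rows.
#' @param ratio True light/heavy area ratio (>= 0).
#' @param run_id Identifier stored with the traces.
#' @return A list with `chromatograms` (tibble: `transition_id`, `run_id`,
#'   `time`, `intensity` list-columns) and `manifest` (true per-transition
#'   areas and the planted ratio).
#' @export
simulate_mrm <- function(config, transitions, ratio, run_id = "run1") {
  stopifnot(inherits(config, "mrm_sim_config"))
  if (nrow(transitions) == 0) abort("transition list is empty")
  if (ratio < 0) abort("ratio must be >= 0")
  tr <- tibble::as_tibble(transitions)
  tr$weight <- NA_real_
  for (iso in unique(tr$isotope)) {
    idx <- which(tr$isotope == iso)
    tr$weight[idx] <- 1 / seq_along(idx)
  }
  tr$true_area <- tr$weight * config$base_area *
    ifelse(tr$isotope == "light", ratio, 1)
  tt <- seq(0, config$duration, by = config$sample_period)
  gauss <- exp(-(tt - config$apex_rt)^2 / (2 * config$sigma_rt^2))
  amp0 <- config$base_area / (config$sigma_rt * sqrt(2 * pi))
  traces <- .with_seed(config$seed, {
    purrr::map(seq_len(nrow(tr)), function(i) {
      amp <- tr$true_area[i] / (config$sigma_rt * sqrt(2 * pi))
      y <- amp * gauss +
        runif(length(tt), 0, config$noise_frac * amp0)
      tibble::tibble(transition_id = tr$transition_id[i], run_id = run_id,
                     time = list(tt), intensity = list(y))
    })
  })
  manifest <- structure(
    list(config = config, ratio = ratio,
         transitions = tr[c("transition_id", "isotope", "true_area")]),
    class = "synthetic_run_manifest")
  list(chromatograms = dplyr::bind_rows(traces), manifest = manifest)
}

#' Write the packaged fixtures to a directory
#'
#' Writes the synthetic substrate FASTA (embedding the conjugatable
#' backbone and its K-to-R variant) and the default DIA simulation
#' settings as YAML. Output is fully deterministic.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "synthetic_substrates.fasta")
  write_fasta(fixture_proteins(), fasta)
  cfgp <- file.path(dir, "sim_config.yaml")
  cfg <- sim_config()
  yaml::write_yaml(unclass(cfg), cfgp)
  invisible(c(fasta = fasta, config = cfgp))
}
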