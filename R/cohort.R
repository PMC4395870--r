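#' Simulate a cohort of embryos through the full imaging pipeline
#'
#' Renders `n_embryos` synthetic embryos (identical geometry, independent
#' noise draws), pushes each through [fret_pipeline()] and the ROI
#' extraction, and returns the embryo-level measurement table. This is the
#' workhorse for calibrating the paired test's power and size on known
#' ground truth.
#'
#' @param n_embryos Number of embryos in the cohort.
#' @param delta_e Ground-truth efficiency drop in the SDR relative to the
#'   rest of the cortex (`e_sdr = e_base - delta_e`); 0 is the null.
#' @param e_base Cortical efficiency outside the SDR.
#' @param shape Acquisition grid, kept small for simulation throughput.
#' @param n_frames z-frames pooled per embryo.
#' @param construct Sensor construct; the force-insensitive controls ignore
#'   `delta_e` by construction.
#' @param params Forward-model parameters (Poisson noise by default).
#' @param calib Calibration used for analysis; defaults to the matched
#'   calibration with 2x2 binning.
#' @param stage Stage label carried into the table.
#' @param seed Integer seed for the whole cohort.
#' @return A tibble with one row per embryo ([pool_embryo()] columns).
#' @examples
#' cohort <- simulate_embryo_cohort(n_embryos = 4, delta_e = 0.1, seed = 7)
#' paired_test(cohort$sdr_mean, cohort$nonsdr_mean)
#' @export
simulate_embryo_cohort <- function(n_embryos = 10,
                                   delta_e = 0.05,
                                   e_base = 0.35,
                                   shape = c(48, 64),
                                   n_frames = 3,
                                   construct = "TSMod",
                                   params = forward_model_params(),
                                   calib = calibration_from_model(params),
                                   stage = "1.5-fold",
                                   seed = 1L) {
  e_sdr <- if (delta_e > 0) e_base - delta_e else e_base
  scene <- tension_scene(shape = shape, e_base = e_base, e_sdr = e_sdr,
                         construct = construct, params = params, seed = seed)
  roi <- roi_from_scene(scene)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_embryos))
  purrr::map_dfr(seq_len(n_embryos), function(i) {
    sim <- simulate_fret_stack(scene, params, n_frames = n_frames,
                               seed = sub_seeds[i])
    fm <- fret_pipeline(sim$stack, calib)
    pool_embryo(extract_roi_values(fm, roi),
                embryo_id = sprintf("embryo%02d", i),
                stage = stage, construct = construct)
  })
}

#' Paired-test p-values over replicated cohorts
#'
#' Repeats [simulate_embryo_cohort()] `n_cohorts` times under one condition
#' and collects the paired-test p-value of SDR vs non-SDR from each cohort.
#' The rejection rate at a chosen alpha estimates power (when `delta_e > 0`)
#' or size (at the null); under the null the p-values should be uniform.
#'
#' @inheritParams simulate_embryo_cohort
#' @param n_cohorts Number of cohort replicates.
#' @return Numeric vector of `n_cohorts` p-values.
#' @export
cohort_paired_pvalues <- function(n_cohorts = 100,
                                  n_embryos = 10,
                                  delta_e = 0.05,
                                  construct = "TSMod",
                                  params = forward_model_params(),
                                  calib = calibration_from_model(params),
                                  shape = c(48, 64),
                                  n_frames = 3,
                                  seed = 1L) {
  e_base <- 0.35
  e_sdr <- if (delta_e > 0) e_base - delta_e else e_base
  scene <- tension_scene(shape = shape, e_base = e_base, e_sdr = e_sdr,
                         construct = construct, params = params, seed = seed)
  # ROI masks at the analysed (binned) scale, fixed across replicates
  f <- calib$bin_factor
  emb <- bin_mask(scene$embryo_mask, f)
  sdr <- box_mask(scale_box(scene$sdr_box, f), dim(emb)) & emb
  nonsdr <- emb & !sdr
  roi_mean <- function(fm, mask) {
    ms <- vapply(seq_len(dim(fm$F)[3]), function(k) {
      sel <- mask & fm$valid[, , k]
      mean(fm$F[, , k][sel])
    }, numeric(1))
    mean(ms, na.rm = TRUE)
  }
  cohort_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_cohorts))
  vapply(seq_len(n_cohorts), function(j) {
    sub_seeds <- withr::with_seed(cohort_seeds[j],
                                  sample.int(.Machine$integer.max, n_embryos))
    vals <- vapply(seq_len(n_embryos), function(i) {
      sim <- simulate_fret_stack(scene, params, n_frames = n_frames,
                                 seed = sub_seeds[i])
      fm <- fret_pipeline(sim$stack, calib)
      c(roi_mean(fm, sdr), roi_mean(fm, nonsdr))
    }, numeric(2))
    paired_test(vals[1, ], vals[2, ])$p.value
  }, numeric(1))
}
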