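make_stack <- function(id, ia, iff, bg = 0) {
  channel_stack(id, ia, iff, background = c(ID = bg, IA = bg, IF = bg))
}

test_that("binning averages blocks and factor 1 is the identity", {
  const <- matrix(7, 8, 8)
  st <- make_stack(const, const, const)
  b <- bin_image(st, 2)
  expect_equal(dim(b$ID), c(4, 4, 1))
  expect_true(all(b$ID == 7))

  m <- matrix(c(1, 3, 2, 4), 2, 2)     # block [1,2;3,4]
  st2 <- make_stack(m, m, m)
  expect_equal(as.numeric(bin_image(st2, 2)$ID), 2.5)

  expect_identical(bin_image(st, 1), st)
  expect_error(bin_image(st, 0), "factor")
})

test_that("background subtraction is scalar, exact and unclipped", {
  st <- make_stack(matrix(100, 4, 4), matrix(100, 4, 4), matrix(100, 4, 4), bg = 20)
  sub <- subtract_background(st)
  expect_true(all(sub$ID == 80))
  st0 <- make_stack(matrix(5, 2, 2), matrix(5, 2, 2), matrix(5, 2, 2), bg = 0)
  expect_equal(subtract_background(st0)$ID, st0$ID)
  stn <- make_stack(matrix(10, 2, 2), matrix(10, 2, 2), matrix(10, 2, 2), bg = 20)
  expect_true(all(subtract_background(stn)$ID == -10))   # retained, not clipped
})

test_that("bleed-through correction follows the pixel-wise equation", {
  IFm <- matrix(100, 3, 3); IDm <- matrix(50, 3, 3); IAm <- matrix(80, 3, 3)
  expect_true(all(correct_bleedthrough(IFm, IDm, IAm, 0.5, 0.2) == 50))
  expect_equal(correct_bleedthrough(IFm, IDm, IAm, 0, 0), IFm)
  over <- correct_bleedthrough(matrix(10, 2, 2), matrix(100, 2, 2),
                               matrix(0, 2, 2), 0, 0.2)
  expect_true(all(over == -10))                          # over-correction retained
  expect_error(correct_bleedthrough(IFm, IDm, matrix(0, 2, 2), 0, 0), "shape")
})

test_that("FRET index obeys its fixed points and invalid-pixel contract", {
  expect_equal(as.numeric(compute_fret_index(matrix(0), matrix(100), 0.5, 2)), 0)
  # numerator equal to quenched donor intensity gives exactly one half
  expect_equal(as.numeric(compute_fret_index(matrix(50), matrix(100), 1, 2)), 0.5)
  f <- compute_fret_index(matrix(c(10, 10)), matrix(c(-1, 0)), 0.5, 2)
  expect_true(all(is.na(f)))
  expect_true(is.na(as.numeric(compute_fret_index(matrix(0), matrix(0), 1, 1))))
})

test_that("index is monotone in its inputs and scale-equivariant", {
  cf <- seq(1, 100, length.out = 50)
  f_cf <- compute_fret_index(matrix(cf), matrix(rep(50, 50)), 0.6, 1.2)
  expect_true(all(diff(as.numeric(f_cf)) > 0))
  qd <- seq(1, 100, length.out = 50)
  f_qd <- compute_fret_index(matrix(rep(30, 50)), matrix(qd), 0.6, 1.2)
  expect_true(all(diff(as.numeric(f_qd)) < 0))
  expect_true(all(f_cf >= 0 & f_cf <= 1))

  # common positive rescaling of all channels and backgrounds cancels
  p <- forward_model_params()
  sc <- small_scene(params = p)
  sim <- simulate_fret_stack(sc, p, seed = 9)
  st <- sim$stack
  st_scaled <- channel_stack(st$ID * 3, st$IA * 3, st$IF * 3,
                             background = st$background * 3)
  cal <- calibration_from_model(p)
  f1 <- fret_pipeline(st, cal)$F_raw
  f2 <- fret_pipeline(st_scaled, cal)$F_raw
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("median filter matches a brute-force sliding-window oracle", {
  expect_equal(median_filter_3x3(matrix(0.2, 5, 5)), matrix(0.2, 5, 5))

  m <- matrix(0.2, 7, 7); m[4, 4] <- 1.0
  expect_equal(median_filter_3x3(m), matrix(0.2, 7, 7))

  brute <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        w <- pad[i:(i + 2), j:(j + 2)]
        out[i, j] <- median(w, na.rm = TRUE)
      }
    }
    out
  }
  set.seed(5)
  r <- matrix(runif(256), 16, 16)
  expect_equal(median_filter_3x3(r), brute(r))

  # invalid pixels are ignored, not propagated
  rn <- r; rn[sample(256, 40)] <- NA
  expect_equal(median_filter_3x3(rn), brute(rn))
  expect_true(all(is.na(median_filter_3x3(matrix(NA_real_, 4, 4)))))
})

test_that("propagated uncertainty follows Poisson scaling", {
  p <- forward_model_params()
  cal <- calibration_from_model(p)
  mu <- pixel_means(1000, 0.35, p)
  s1 <- propagate_uncertainty(one_pixel_stack(mu, p$background), cal)
  # quadrupling every channel and background at fixed F halves sigma_F
  s4 <- propagate_uncertainty(one_pixel_stack(mu * 4, p$background * 4), cal)
  expect_gt(as.numeric(s1), 0)
  expect_equal(as.numeric(s4) / as.numeric(s1), 0.5, tolerance = 1e-12)

  # vanishing gain limit and invalid gain
  cal_small <- calibration_from_model(p, noise_gain = 1e-12)
  expect_lt(as.numeric(propagate_uncertainty(one_pixel_stack(mu, p$background),
                                             cal_small)), 1e-5)
  expect_error(calibration_params(noise_gain = 0), "noise_gain")
})

test_that("intensity threshold selects the sensor-rich cortex", {
  p <- forward_model_params()
  sc <- small_scene(params = p)
  sim <- simulate_fret_stack(sc, p, n_frames = 1, seed = 21)
  cal <- calibration_from_model(p, bin_factor = 1)
  mask <- threshold_pixels(sim$stack, cal)[, , 1]
  expect_gte(mean(mask[sc$cortex_mask]), 0.9)
  expect_lte(mean(mask[!sc$embryo_mask]), 0.05)

  # everything below threshold: empty mask with a warning
  dark <- make_stack(matrix(1, 4, 4), matrix(1, 4, 4), matrix(1, 4, 4), bg = 100)
  expect_warning(m0 <- threshold_pixels(dark, cal), "no pixels")
  expect_false(any(m0))

  # k = 0 with zero background: every sensor-bearing pixel passes
  p0 <- noiseless_params(background = 0)
  sim0 <- simulate_fret_stack(small_scene(params = p0), p0, n_frames = 1)
  cal0 <- calibration_from_model(p0, threshold_k = 0, bin_factor = 1)
  m <- threshold_pixels(sim0$stack, cal0)[, , 1]
  expect_true(all(m[sim0$scene$cortex_mask]))
})

test_that("FRET tracks expression only when transfer is intermolecular", {
  # uniform tension: any F / acceptor-count correlation would be an
  # expression artifact (the +/-30% expression gradient stays on)
  p <- forward_model_params(sensor_density = 1000)
  sc <- tension_scene(shape = c(96, 128), e_sdr = 0.35, params = p, seed = 13)
  sim <- simulate_fret_stack(sc, p, n_frames = 3, seed = 13)
  fm <- fret_pipeline(sim$stack, calibration_from_model(p))
  r <- expression_independence(fm, sim$stack)
  expect_gt(r$n, 100)
  expect_lt(abs(r$r), 0.1)

  # adversarial control: intermolecular contamination must be detected
  p_inter <- forward_model_params(sensor_density = 1000, intermolecular = 0.3)
  sim2 <- simulate_fret_stack(sc, p_inter, n_frames = 3, seed = 13)
  fm2 <- fret_pipeline(sim2$stack, calibration_from_model(p_inter))
  r2 <- expression_independence(fm2, sim2$stack)
  expect_gt(abs(r2$r), 0.3)
})
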