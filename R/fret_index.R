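#' Calibration parameters for the FRET-index pipeline
#'
#' The pipeline needs four measured instrument constants plus a noise model
#' and a pixel-filter rule. The bleed-through fractions and collection
#' efficiencies are instrument properties that must be calibrated on
#' donor-only / acceptor-only samples; they are required configuration inputs
#' here and the defaults are documented placeholders that match the synthetic
#' imager's own defaults.
#'
#' @param alpha Acceptor bleed-through fraction into the raw FRET channel.
#' @param delta Donor bleed-through fraction into the raw FRET channel.
#' @param qd Donor quantum yield.
#' @param phi_ratio Collection-efficiency ratio phiD/phiA (the acceptor
#'   quantum yield is folded into phiA).
#' @param noise_gain Counts per detected photon in the shot-noise variance
#'   model `Var(channel) = noise_gain * channel`.
#' @param threshold_k Pixel-filter multiplier: a pixel is kept when its
#'   acceptor-channel intensity exceeds `background + k * SD(background)`.
#' @param bin_factor Integer downsample-and-average factor applied exactly
#'   once before any processing.
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(alpha = 0.1, delta = 0.15, qd = 0.6,
                               phi_ratio = 1.2, noise_gain = 1,
                               threshold_k = 2, bin_factor = 2) {
  if (alpha < 0 || alpha >= 1 || delta < 0 || delta >= 1) {
    abort("bleed-through fractions must lie in [0, 1)")
  }
  stopifnot(qd > 0, qd <= 1, phi_ratio > 0, threshold_k >= 0, bin_factor >= 1)
  if (noise_gain <= 0) abort("`noise_gain` must be positive")
  structure(list(alpha = alpha, delta = delta, qd = qd, phi_ratio = phi_ratio,
                 noise_gain = noise_gain, threshold_k = threshold_k,
                 bin_factor = as.integer(bin_factor)),
            class = "calibration_params")
}

#' @rdname calibration_params
#' @param params A [forward_model_params()] whose optical constants should be
#'   used (the matched calibration for synthetic data).
#' @param ... Overrides passed on to [calibration_params()].
#' @export
calibration_from_model <- function(params, ...) {
  dots <- list(...)
  args <- list(alpha = params$alpha, delta = params$delta, qd = params$qd,
               phi_ratio = params$phi_d / params$phi_a)
  do.call(calibration_params, utils::modifyList(args, dots))
}

bin_matrix <- function(m, f) {
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  dim(m) <- c(f, nr, nc * f)
  m <- colMeans(m)                  # nr x (nc*f)
  m <- t(m)
  dim(m) <- c(f, nc, nr)
  t(colMeans(m))                    # nr x nc
}

each_frame <- function(a, .fn, ...) {
  out <- lapply(seq_len(dim(a)[3]), function(k) .fn(a[, , k], ...))
  array(unlist(out), c(dim(out[[1]]), length(out)))
}

#' Downsample-and-average binning
#'
#' Replaces each `factor x factor` block by its arithmetic mean, once, to
#' raise the per-pixel signal-to-noise ratio. Trailing rows/columns that do
#' not fill a complete block are cropped.
#'
#' @param stack A [channel_stack()].
#' @param factor Integer binning factor (`1` is the identity).
#' @return A binned [channel_stack()] (backgrounds are unchanged: the mean of
#'   a constant is itself).
#' @export
bin_image <- function(stack, factor = 2) {
  stopifnot(inherits(stack, "channel_stack"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    abort("`factor` must be a single integer >= 1")
  }
  if (factor == 1) return(stack)
  channel_stack(each_frame(stack$ID, bin_matrix, f = factor),
                each_frame(stack$IA, bin_matrix, f = factor),
                each_frame(stack$IF, bin_matrix, f = factor),
                background = stack$background)
}

#' Scalar background subtraction
#'
#' Subtracts each channel's scalar background estimate. Negative results are
#' retained (not clipped); they are handled later by the validity mask.
#'
#' @param stack A [channel_stack()] with background estimates.
#' @return A [channel_stack()] with zeroed background fields and an
#'   `attr(, "subtracted")` record of what was removed.
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  bg <- stack$background
  if (anyNA(bg)) abort("background estimates are missing")
  out <- channel_stack(stack$ID - bg["ID"], stack$IA - bg["IA"],
                       stack$IF - bg["IF"], background = c(ID = 0, IA = 0, IF = 0))
  attr(out, "subtracted") <- bg
  out
}

#' Spectral bleed-through correction
#'
#' Removes the donor and direct-acceptor contamination from the raw FRET
#' channel, pixel by pixel:
#' `cF(i, j) = IF(i, j) - delta * ID(i, j) - alpha * IA(i, j)`.
#' Over-corrected (negative) pixels are retained and left to the validity
#' mask.
#'
#' @param IF,ID,IA Background-subtracted intensity maps of identical shape
#'   (matrices or arrays).
#' @param alpha,delta Bleed-through fractions.
#' @return The corrected sensitized-emission map `cF`, same shape.
#' @export
correct_bleedthrough <- function(IF, ID, IA, alpha, delta) {
  if (!identical(dim(IF), dim(ID)) || !identical(dim(IF), dim(IA))) {
    abort("`IF`, `ID` and `IA` must have identical shapes")
  }
  IF - delta * ID - alpha * IA
}

#' Pixel-wise FRET index
#'
#' The sensitized-emission index
#' `F = (cF * qd * phi_ratio) / (qD + cF * qd * phi_ratio)`:
#' the fraction of donor excitations that ended in transfer, reconstructed
#' from the corrected FRET channel `cF` and the quenched donor intensity
#' `qD`. Pixels where `qD <= 0`, or where numerator and denominator both
#' vanish, are marked invalid (`NA`) rather than propagating NaN.
#'
#' @param cF Corrected sensitized-emission map ([correct_bleedthrough()]).
#' @param qD Quenched donor intensity map (background-subtracted donor
#'   channel).
#' @param qd Donor quantum yield.
#' @param phi_ratio Collection-efficiency ratio phiD/phiA.
#' @return FRET-index map, same shape; `NA` at invalid pixels.
#' @export
compute_fret_index <- function(cF, qD, qd, phi_ratio) {
  if (!identical(dim(cF), dim(qD))) abort("`cF` and `qD` must have identical shapes")
  num <- cF * qd * phi_ratio
  f <- num / (qD + num)
  f[qD <= 0 | (qD + num) == 0] <- NA_real_
  f
}

sort9_network <- function(vs) {
  # bubble network: correctness is structural, speed comes from vectorisation
  for (p in 1:8) {
    for (i in seq_len(9 - p)) {
      a <- vs[[i]]; b <- vs[[i + 1]]
      vs[[i]] <- pmin(a, b)
      vs[[i + 1]] <- pmax(a, b)
    }
  }
  vs
}

#' 3 x 3 median filter
#'
#' Replaces every pixel by the median of its 3 x 3 neighbourhood to remove
#' high-frequency noise from the index map. The border is reflect-padded
#' (edge pixels are mirrored outward), and `NA` neighbours — invalid pixels —
#' are ignored: each output pixel is the median of the finite values in its
#' window (`NA` only where the whole window is invalid).
#'
#' @param m Numeric matrix (or `rows x cols x frames` array, filtered
#'   frame-wise).
#' @param min_valid Minimum number of finite values a window must contain
#'   for its median to be defined (`NA` otherwise). The default 1 filters
#'   wherever any information exists; the pipeline uses a majority rule so
#'   that isolated pixels surrounded by invalid neighbours do not pass
#'   through unsmoothed.
#' @return Filtered map of the same shape.
#' @export
median_filter_3x3 <- function(m, min_valid = 1) {
  if (length(dim(m)) == 3) return(each_frame(m, median_filter_3x3, min_valid = min_valid))
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  vs <- vector("list", 9)
  idx <- 1
  for (di in 0:2) {
    for (dj in 0:2) {
      vs[[idx]] <- as.numeric(pad[di + seq_len(nr), dj + seq_len(nc)])
      idx <- idx + 1
    }
  }
  n_na <- Reduce(`+`, lapply(vs, is.na))
  vs <- lapply(vs, function(v) { v[is.na(v)] <- Inf; v })
  s <- sort9_network(vs)
  k <- 9L - n_na
  smat <- matrix(unlist(s), ncol = 9)
  n <- nr * nc
  lo <- pmax(1L, (k + 1L) %/% 2L)
  hi <- pmax(1L, k %/% 2L + 1L)
  out <- (smat[cbind(seq_len(n), lo)] + smat[cbind(seq_len(n), hi)]) / 2
  out[k < max(1L, min_valid)] <- NA_real_
  matrix(out, nr, nc)
}

#' First-order shot-noise propagation to the FRET index
#'
#' Propagates the per-channel shot-noise variance
#' `Var(channel) = noise_gain * channel / bin_area` through the bleed-through
#' correction and the index formula, using the analytic partial derivatives
#' of `F` with respect to the three raw channels:
#' \deqn{\sigma_F^2 = (\partial F/\partial I_F)^2 \sigma_{I_F}^2 +
#'   (\partial F/\partial I_D)^2 \sigma_{I_D}^2 +
#'   (\partial F/\partial I_A)^2 \sigma_{I_A}^2.}
#' Low-intensity pixels therefore show high uncertainty, and scaling all
#' channels up at fixed `F` shrinks `sigma_F` like one over the square root
#' of intensity.
#'
#' @param stack A (possibly binned) [channel_stack()] with raw (pre-
#'   subtraction) intensities and background estimates.
#' @param calib A [calibration_params()].
#' @param bin_area Number of acquisition pixels averaged into each pixel of
#'   `stack` (binning divides the variance of the mean by this factor).
#' @return Array of per-pixel `sigma_F` values (`NA` at invalid pixels).
#' @export
propagate_uncertainty <- function(stack, calib, bin_area = 1) {
  stopifnot(inherits(stack, "channel_stack"), inherits(calib, "calibration_params"))
  bg <- stack$background
  qD <- stack$ID - bg["ID"]
  cF <- correct_bleedthrough(stack$IF - bg["IF"], qD, stack$IA - bg["IA"],
                             calib$alpha, calib$delta)
  cc <- calib$qd * calib$phi_ratio
  num <- cF * cc
  den2 <- (qD + num)^2
  d_if <- cc * qD / den2
  d_id <- -(calib$delta * cc * qD + num) / den2
  d_ia <- -calib$alpha * cc * qD / den2
  g <- calib$noise_gain / bin_area
  v <- d_if^2 * g * pmax(stack$IF, 0) +
    d_id^2 * g * pmax(stack$ID, 0) +
    d_ia^2 * g * pmax(stack$IA, 0)
  s <- sqrt(v)
  s[qD <= 0 | den2 == 0] <- NA_real_
  s
}

#' Intensity-based pixel filter
#'
#' Keeps pixels whose acceptor-channel intensity exceeds
#' `background + k * SD(background)`, with the background SD taken from the
#' shot-noise model `SD = sqrt(noise_gain * background / bin_area)`. Because
#' the sensor concentrates at cell cortices, this both removes high-
#' uncertainty dim pixels and selects the sensor-rich cortical domains.
#'
#' @inheritParams propagate_uncertainty
#' @return Logical array, `TRUE` where the pixel passes the filter.
#' @export
threshold_pixels <- function(stack, calib, bin_area = 1) {
  stopifnot(inherits(stack, "channel_stack"))
  bg <- stack$background["IA"]
  cut <- bg + calib$threshold_k * sqrt(calib$noise_gain * bg / bin_area)
  mask <- stack$IA > cut
  if (!any(mask)) warn("pixel filter kept no pixels: every intensity is below threshold")
  mask
}

#' Full FRET-index pipeline
#'
#' Runs the fixed processing order on a raw three-channel stack:
#' bin once, subtract backgrounds, correct bleed-through, compute the
#' pixel-wise index, median-filter (optional), propagate shot-noise
#' uncertainty and apply the intensity filter.
#'
#' @param stack A raw [channel_stack()].
#' @param calib A [calibration_params()].
#' @param median_filter Apply the 3 x 3 median filter to the index map
#'   (default `TRUE`). Disable for pixel-exact validation of the index
#'   algebra: the filter mixes values across region boundaries.
#' @return An object of class `fret_map`: list with arrays `F` (filtered
#'   index), `F_raw` (pre-filter), `sigma_f`, `valid`, `qD`, `cF`, plus
#'   `bin_factor` and the calibration used.
#' @examples
#' sim <- simulate_fret_stack(tension_scene(shape = c(48, 64)),
#'                            forward_model_params(noise = "none"))
#' fm <- fret_pipeline(sim$stack, calibration_from_model(sim$params, bin_factor = 1),
#'                     median_filter = FALSE)
#' @export
fret_pipeline <- function(stack, calib = calibration_params(), median_filter = TRUE) {
  stopifnot(inherits(stack, "channel_stack"), inherits(calib, "calibration_params"))
  binned <- bin_image(stack, calib$bin_factor)
  bin_area <- calib$bin_factor^2
  sub <- subtract_background(binned)
  cF <- correct_bleedthrough(sub$IF, sub$ID, sub$IA, calib$alpha, calib$delta)
  qD <- sub$ID
  f_raw <- compute_fret_index(cF, qD, calib$qd, calib$phi_ratio)
  intense <- threshold_pixels(binned, calib, bin_area = bin_area)
  f <- if (median_filter) {
    # restrict the filter to sensor-bearing pixels: index values below the
    # intensity threshold are dominated by noise and would contaminate the
    # windows of genuine cortical pixels
    f_mask <- f_raw
    f_mask[!intense] <- NA_real_
    median_filter_3x3(f_mask, min_valid = 5)
  } else {
    f_raw
  }
  sigma_f <- propagate_uncertainty(binned, calib, bin_area = bin_area)
  valid <- intense & !is.na(f_raw) & !is.na(f)
  structure(list(F = f, F_raw = f_raw, sigma_f = sigma_f, valid = valid,
                 qD = qD, cF = cF, bin_factor = calib$bin_factor, calib = calib),
            class = "fret_map")
}

#' @export
print.fret_map <- function(x, ...) {
  d <- dim(x$F)
  cat(sprintf("<fret_map> %d x %d px, %d frame(s); %.1f%% valid; median F (valid) = %.3f\n",
              d[1], d[2], d[3], 100 * mean(x$valid),
              median(x$F[x$valid], na.rm = TRUE)))
  invisible(x)
}
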