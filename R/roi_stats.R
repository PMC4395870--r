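#' Region-of-interest specification for one embryo
#'
#' The tension read-out compares a small box over the sensory depression
#' region (SDR, the pharynx attachment site) against the remainder of the
#' embryo (non-SDR), so that both regions share the exact same imaging
#' history. The non-SDR region is the embryo footprint minus the SDR box;
#' the two are disjoint by construction.
#'
#' @param sdr_box Integer vector `c(row0, row1, col0, col1)`, 0-based,
#'   half-open, in acquisition-pixel coordinates.
#' @param embryo_mask Logical matrix of the embryo footprint at acquisition
#'   scale.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(sdr_box, embryo_mask) {
  sdr <- box_mask(sdr_box, dim(embryo_mask)) & embryo_mask
  nonsdr <- embryo_mask & !sdr
  if (!any(sdr)) abort("SDR box contains no embryo pixels")
  if (!any(nonsdr)) abort("non-SDR region is empty")
  structure(list(sdr_box = as.integer(sdr_box), embryo_mask = embryo_mask),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @param scene A [tension_scene()]; its ground-truth box and footprint
#'   become the ROI (on synthetic data the SDR is known, not hand-drawn).
#' @export
roi_from_scene <- function(scene) {
  roi_spec(scene$sdr_box, scene$embryo_mask)
}

bin_mask <- function(mask, f) {
  if (f == 1) return(mask)
  bin_matrix(mask + 0, f) >= 0.5
}

scale_box <- function(box, f) {
  as.integer(c(box[1] %/% f, ceiling(box[2] / f),
               box[3] %/% f, ceiling(box[4] / f)))
}

#' Per-frame ROI means of the FRET index
#'
#' Averages the index over the valid pixels of the SDR and non-SDR regions
#' in every z-frame. Frames in which either region retains no valid pixel
#' are dropped with a warning; if no frame survives, this is an error.
#'
#' @param fret_map A [fret_pipeline()] result.
#' @param roi A [roi_spec()] in acquisition coordinates (rescaled internally
#'   to the map's binning).
#' @return A tibble with columns `frame`, `sdr_mean`, `nonsdr_mean`,
#'   `n_valid_sdr`, `n_valid_nonsdr`.
#' @export
extract_roi_values <- function(fret_map, roi) {
  stopifnot(inherits(fret_map, "fret_map"), inherits(roi, "roi_spec"))
  f <- fret_map$bin_factor
  emb <- bin_mask(roi$embryo_mask, f)
  sdr <- box_mask(scale_box(roi$sdr_box, f), dim(emb)) & emb
  nonsdr <- emb & !sdr
  if (!any(sdr) || !any(nonsdr)) abort("ROI is empty after rescaling to the binned grid")

  rows <- purrr::map_dfr(seq_len(dim(fret_map$F)[3]), function(k) {
    fk <- fret_map$F[, , k]
    vk <- fret_map$valid[, , k]
    tibble::tibble(
      frame = k,
      sdr_mean = mean(fk[sdr & vk]),
      nonsdr_mean = mean(fk[nonsdr & vk]),
      n_valid_sdr = sum(sdr & vk),
      n_valid_nonsdr = sum(nonsdr & vk)
    )
  })
  bad <- rows$n_valid_sdr == 0 | rows$n_valid_nonsdr == 0
  if (any(bad)) {
    warn(sprintf("dropping %d frame(s) with an empty valid ROI", sum(bad)))
    rows <- rows[!bad, ]
  }
  if (nrow(rows) == 0) abort("every frame had an empty valid ROI")
  rows
}

#' Pool per-frame ROI values into one embryo-level measurement
#'
#' The per-frame SDR and non-SDR means from the planes encompassing the
#' buccal cavity are pooled by an unweighted average; that average is the
#' embryo's experimental value.
#'
#' @param roi_values Output of [extract_roi_values()].
#' @param embryo_id,stage,construct Labels carried through to the result.
#' @return A one-row tibble (`embryo_id`, `stage`, `construct`, `sdr_mean`,
#'   `nonsdr_mean`, `n_frames`, `n_valid_sdr`, `n_valid_nonsdr`).
#' @export
pool_embryo <- function(roi_values, embryo_id = "embryo1",
                        stage = "1.5-fold", construct = "TSMod") {
  stopifnot(nrow(roi_values) >= 1)
  tibble::tibble(
    embryo_id = embryo_id, stage = stage, construct = construct,
    sdr_mean = mean(roi_values$sdr_mean),
    nonsdr_mean = mean(roi_values$nonsdr_mean),
    n_frames = nrow(roi_values),
    n_valid_sdr = mean(roi_values$n_valid_sdr),
    n_valid_nonsdr = mean(roi_values$n_valid_nonsdr)
  )
}

test_row <- function(method, estimate, statistic, df, p) {
  tibble::tibble(method = method, estimate = estimate,
                 statistic = statistic, df = df, p.value = p)
}

#' Paired two-tailed t test on per-embryo ROI means
#'
#' Compares SDR against non-SDR values embryo by embryo (each embryo is its
#' own control, so sensor expression level and imaging conditions cancel).
#' Zero variance of the differences is reported as the exact limiting case
#' (p = 1 when every difference is zero, p = 0 otherwise) with a warning.
#'
#' @param x,y Equal-length paired vectors of per-embryo means (n >= 2).
#' @return A one-row tibble: `method`, `estimate` (mean difference),
#'   `statistic`, `df`, `p.value`.
#' @export
paired_test <- function(x, y) {
  if (length(x) != length(y)) abort("paired vectors must have equal length")
  if (length(x) < 2) abort("need at least two pairs")
  d <- x - y
  if (sd(d) == 0) {
    warn("zero variance of paired differences: p-value is the exact limit case")
    p <- if (all(d == 0)) 1 else 0
    stat <- if (all(d == 0)) 0 else Inf * sign(mean(d))
    return(test_row("paired t-test", mean(d), stat, length(d) - 1, p))
  }
  tt <- t.test(x, y, paired = TRUE)
  test_row("paired t-test", unname(tt$estimate), unname(tt$statistic),
           unname(tt$parameter), tt$p.value)
}

#' Two-sample two-tailed t test
#'
#' Classical pooled-variance Student form by default (the companion
#' equal-variance check is [assumption_checks()]'s Levene test); Welch's
#' unequal-variance form behind `var_equal = FALSE`.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @param var_equal Use the pooled-variance form (default `TRUE`).
#' @return A one-row tibble as in [paired_test()]; `estimate` is the mean
#'   difference `mean(x) - mean(y)`.
#' @export
unpaired_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("need at least two values per group")
  if (sd(x) == 0 && sd(y) == 0) {
    warn("zero variance in both groups: p-value is the exact limit case")
    d <- mean(x) - mean(y)
    return(test_row("two-sample t-test", d,
                    if (d == 0) 0 else Inf * sign(d),
                    length(x) + length(y) - 2, if (d == 0) 1 else 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  test_row(if (var_equal) "two-sample t-test (pooled)" else "Welch t-test",
           unname(tt$estimate[1] - tt$estimate[2]), unname(tt$statistic),
           unname(tt$parameter), tt$p.value)
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + K^2/4)` with moment-based sample skewness `S` and
#' excess kurtosis `K`, referred to a chi-square distribution with two
#' degrees of freedom.
#'
#' @param x Numeric vector, n >= 3.
#' @return A one-row tibble (`method`, `statistic`, `df`, `p.value`).
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) abort("Jarque-Bera needs at least 3 observations")
  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  if (m2 == 0) abort("constant sample: skewness and kurtosis are undefined")
  s <- m3 / m2^1.5
  k <- m4 / m2^2 - 3
  jb <- n / 6 * (s^2 + k^2 / 4)
  tibble::tibble(method = "Jarque-Bera", statistic = jb, df = 2,
                 p.value = pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Distributional assumption checks for the t-test battery
#'
#' Jarque-Bera normality on the pooled values and (when a grouping is given)
#' Levene's equal-variance test centred at the group means (the original
#' Levene form).
#'
#' @param x Numeric vector of values.
#' @param g Optional factor of group labels (>= 2 groups) for Levene.
#' @return A tibble with one row per test (`method`, `statistic`, `df`,
#'   `p.value`).
#' @export
assumption_checks <- function(x, g = NULL) {
  out <- jarque_bera(x)
  if (!is.null(g)) {
    g <- factor(g)
    if (nlevels(g) < 2) abort("Levene's test needs at least two groups")
    lev <- car::leveneTest(x, g, center = mean)
    out <- dplyr::bind_rows(out, tibble::tibble(
      method = "Levene (mean-centred)", statistic = lev[1, "F value"],
      df = lev[1, "Df"], p.value = lev[1, "Pr(>F)"]))
  }
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups: exact enumeration when both groups
#' have at most 20 untied observations, otherwise the normal approximation
#' with mid-rank tie handling and variance correction.
#'
#' @param x,y Numeric vectors.
#' @return A one-row tibble (`method`, `statistic` = U for the first group,
#'   `p.value`).
#' @export
mann_whitney <- function(x, y) {
  ties <- any(duplicated(c(x, y)))
  if (ties && all(c(x, y) == c(x, y)[1])) {
    warn("all values tied: U at its midpoint, p = 1")
    return(tibble::tibble(method = "Mann-Whitney U", statistic = length(x) * length(y) / 2,
                          p.value = 1))
  }
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(method = "Mann-Whitney U", statistic = unname(wt$statistic),
                 p.value = wt$p.value)
}

#' FRET-expression independence check
#'
#' For an intramolecular sensor the index must not depend on how much sensor
#' a pixel contains. Reports the Pearson correlation between valid-pixel
#' index values and acceptor-channel counts (the expression proxy); |r|
#' materially above zero indicates intermolecular transfer or a correction
#' failure.
#'
#' @param fret_map A [fret_pipeline()] result.
#' @param stack The raw [channel_stack()] the map was computed from.
#' @return A one-row tibble (`r`, `n`); `r` is `NA` with a warning when
#'   either variable is constant.
#' @export
expression_independence <- function(fret_map, stack) {
  binned <- bin_image(stack, fret_map$bin_factor)
  f <- fret_map$F[fret_map$valid]
  a <- binned$IA[fret_map$valid]
  keep <- is.finite(f) & is.finite(a)
  f <- f[keep]; a <- a[keep]
  if (length(f) < 10) abort("need at least 10 valid pixels")
  if (sd(f) == 0 || sd(a) == 0) {
    warn("constant input: correlation undefined")
    return(tibble::tibble(r = NA_real_, n = length(f)))
  }
  tibble::tibble(r = cor(f, a), n = length(f))
}
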