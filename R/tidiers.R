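#' Tidy a FRET map into a per-pixel table
#'
#' @param x A [fret_pipeline()] result.
#' @param valid_only Keep only pixels that pass the validity mask.
#' @param ... Unused.
#' @return A tibble with `frame`, `row`, `col` (0-based), `f`, `sigma_f`,
#'   `valid`.
#' @export
tidy.fret_map <- function(x, valid_only = FALSE, ...) {
  d <- dim(x$F)
  out <- tibble::tibble(
    frame = rep(seq_len(d[3]), each = d[1] * d[2]),
    row = rep(rep(seq_len(d[1]) - 1L, d[2]), d[3]),
    col = rep(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    f = as.numeric(x$F),
    sigma_f = as.numeric(x$sigma_f),
    valid = as.logical(x$valid)
  )
  if (valid_only) out <- out[out$valid, ]
  out
}

#' One-row summary of a FRET map
#'
#' @param x A [fret_pipeline()] result.
#' @param ... Unused.
#' @return A tibble with pixel counts, valid fraction and the valid-pixel
#'   index and uncertainty summaries.
#' @export
glance.fret_map <- function(x, ...) {
  v <- x$valid
  tibble::tibble(
    n_pixels = length(x$F),
    n_frames = dim(x$F)[3],
    frac_valid = mean(v),
    f_median = median(x$F[v], na.rm = TRUE),
    f_mean = mean(x$F[v], na.rm = TRUE),
    sigma_f_median = median(x$sigma_f[v], na.rm = TRUE)
  )
}

#' Tidy a synthetic splice simulation
#'
#' @param x A [simulate_probe_table()] result.
#' @param ... Unused.
#' @return The probe tibble with the ground-truth category joined on.
#' @export
tidy.splice_sim <- function(x, ...) {
  dplyr::left_join(x$probes,
                   dplyr::select(x$truth, "region_id", truth_category = "category"),
                   by = "region_id") |>
    dplyr::mutate(truth_category = tidyr::replace_na(.data$truth_category, "none"))
}

#' @export
glance.splice_sim <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$annotation),
    n_regions = dplyr::n_distinct(x$probes$region_id),
    n_probes = nrow(x$probes) / 2,
    n_planted = nrow(x$truth),
    as_fraction = mean(x$annotation$as_flag)
  )
}
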