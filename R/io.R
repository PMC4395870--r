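#' Write a three-channel stack as multi-page TIFF
#'
#' Pages are ordered z-major, channel-minor (frame 1: ID, IA, IF; frame 2:
#' ID, IA, IF; ...). Integer count data (Poisson-noise stacks) are stored as
#' 16-bit with an exact round trip; non-integer (noiseless expectation)
#' data are stored as 32-bit float with a scale factor. The layout, channel
#' order, storage mode, scale and background estimates are recorded in a
#' YAML sidecar `<path>.meta.yml`.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  pages <- list()
  for (k in seq_len(stack$n_frames)) {
    pages <- c(pages, list(stack$ID[, , k], stack$IA[, , k], stack$IF[, , k]))
  }
  vals <- unlist(pages)
  int_mode <- all(vals == round(vals)) && min(vals) >= 0 && max(vals) <= 65535
  if (int_mode) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(abs(vals), 1)
    bits <- 32L
  }
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = bits, compression = "none")
  yaml::write_yaml(list(
    format = "fretsplice-stack-v1",
    page_order = "z-major, channel-minor",
    channels = c("ID", "IA", "IF"),
    n_frames = stack$n_frames,
    storage = if (int_mode) "uint16" else "float32",
    scale = scale,
    background = as.list(stack$background)
  ), paste0(path, ".meta.yml"))
  invisible(path)
}

#' Read a three-channel stack written by [write_stack()]
#'
#' Validates the documented layout (page count a multiple of three, all
#' pages the same shape) and names the offending page on violations.
#'
#' @param path TIFF path (its `<path>.meta.yml` sidecar must exist).
#' @return A [channel_stack()].
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".meta.yml")
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (!file.exists(meta_path)) abort(sprintf("missing stack metadata sidecar: %s", meta_path))
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$format, "fretsplice-stack-v1")) {
    abort("unrecognised stack format (expected fretsplice-stack-v1 metadata)")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 3 != 0) {
    abort(sprintf(
      "layout violation: %d page(s); the z-major/channel-minor layout requires 3 pages (ID, IA, IF) per frame",
      length(pages)))
  }
  n_frames <- length(pages) / 3
  if (!is.null(meta$n_frames) && meta$n_frames != n_frames) {
    abort(sprintf("metadata declares %d frame(s) but the file holds %d", meta$n_frames, n_frames))
  }
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d1)) {
      abort(sprintf("ragged stack: page %d has shape %s, expected %s",
                    i, paste(dim(pages[[i]]), collapse = "x"),
                    paste(d1, collapse = "x")))
    }
  }
  scale <- meta$scale %||% 1
  grab <- function(offset) {
    a <- array(0, c(d1, n_frames))
    for (k in seq_len(n_frames)) {
      p <- pages[[(k - 1) * 3 + offset]] * scale
      if (identical(meta$storage, "uint16")) p <- round(p)
      a[, , k] <- p
    }
    a
  }
  bg <- unlist(meta$background)[c("ID", "IA", "IF")]
  channel_stack(grab(1), grab(2), grab(3), background = bg)
}

#' Write / read a single-channel map as 32-bit float TIFF
#'
#' Used for ground-truth efficiency maps and computed F / sigma-F maps.
#' Finite values are affinely mapped into [0.5, 1] (the range limits are
#' recorded in a sidecar); `NA`s are stored as 0 and restored on read.
#'
#' @param m Numeric matrix or `rows x cols x frames` array.
#' @param path Output path.
#' @return `path` (write) or the restored array (read).
#' @export
write_map <- function(m, path) {
  a <- if (length(dim(m)) == 2) array(m, c(dim(m), 1L)) else m
  fin <- a[is.finite(a)]
  lo <- if (length(fin)) min(fin) else 0
  hi <- if (length(fin)) max(fin) else 1
  if (hi == lo) hi <- lo + 1
  pages <- lapply(seq_len(dim(a)[3]), function(k) {
    p <- 0.5 + 0.5 * (a[, , k] - lo) / (hi - lo)
    p[!is.finite(p)] <- 0
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(list(format = "fretsplice-map-v1", lo = lo, hi = hi,
                        n_frames = dim(a)[3]), paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    v <- meta$lo + (p - 0.5) * 2 * (meta$hi - meta$lo)
    v[p < 0.25] <- NA
    a[, , k] <- v
  }
  a
}

#' Read a calibration file
#'
#' Flat key-value YAML holding the [calibration_params()] fields; unknown
#' keys are an error (fail-fast against typos), missing keys fall back to
#' the documented defaults.
#'
#' @param path YAML file path.
#' @return A [calibration_params()].
#' @export
read_calibration <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(calibration_params))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    abort(sprintf("unknown calibration key(s): %s", paste(extra, collapse = ", ")))
  }
  do.call(calibration_params, vals)
}

#' @rdname read_calibration
#' @param calib A [calibration_params()] to serialise.
#' @export
write_calibration <- function(calib, path) {
  yaml::write_yaml(unclass(calib), path)
  invisible(path)
}

#' Write a table as TSV with a provenance header
#'
#' Every output table carries comment lines recording the package version,
#' the run seed and a hash of the resolved configuration, so any artifact
#' can be traced to the exact run that produced it.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Optional run configuration (hashed into the header).
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fretsplice %s",
                     as.character(utils::packageVersion("fretsplice"))), con)
  if (!is.null(config) || !is.null(seed)) {
    writeLines(sprintf("# config_hash=%s seed=%s",
                       if (is.null(config)) "none" else config_hash(config),
                       if (is.null(seed)) "none" else seed), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_prov
#' @export
read_tsv_prov <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
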