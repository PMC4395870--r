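#' Ground-truth imaging scene for a tension-sensor embryo
#'
#' Builds the geometry and tension field that the synthetic imager renders:
#' an elliptical embryo footprint, a thin cortical band where the
#' spectrin-bound sensor concentrates, and a small rectangular
#' sensory-depression region (SDR) on the anterior cortex where tension is
#' elevated (hence FRET is reduced). The tension values are chosen so that
#' the ground-truth efficiencies on the cortex equal `e_base` outside and
#' `e_sdr` inside the SDR box for the force-sensitive construct.
#'
#' Coordinates are 0-based row/column and boxes are half-open intervals
#' `[row0, row1) x [col0, col1)`, matching the convention used by the ROI
#' operations.
#'
#' @param shape Integer vector `c(rows, cols)` of the acquisition grid.
#' @param cortex_width Width of the cortical band in acquisition pixels. The
#'   default (6) leaves a 2-3 px band after the default 2x2 analysis binning.
#' @param sdr_size Side lengths `c(rows, cols)` of the SDR box.
#' @param e_base,e_sdr Ground-truth FRET efficiency on the cortex outside and
#'   inside the SDR (force-sensitive construct only).
#' @param construct One of `"TSMod"` (force-sensitive), `"N-TSMod"` (terminal
#'   fusion, no force transmission), `"5aa"` (short rigid linker, high FRET)
#'   or `"TRAF"` (long separator, low FRET).
#' @param params [forward_model_params()] used to convert the target
#'   efficiencies into tensions.
#' @param seed Integer seed recorded in the scene (the imager draws all of
#'   its noise from it).
#'
#' @return An object of class `tension_scene`: a list with `shape`,
#'   `embryo_mask`, `cortex_mask`, `force_field`, `sdr_box` (0-based,
#'   half-open `c(row0, row1, col0, col1)`), `construct` and `seed`.
#' @examples
#' sc <- tension_scene(shape = c(60, 80), seed = 1)
#' table(sc$cortex_mask)
#' @export
tension_scene <- function(shape = c(96, 128),
                          cortex_width = 6,
                          sdr_size = c(16, 14),
                          e_base = 0.35,
                          e_sdr = 0.20,
                          construct = c("TSMod", "N-TSMod", "5aa", "TRAF"),
                          params = forward_model_params(),
                          seed = 1L) {
  construct <- match.arg(construct)
  stopifnot(length(shape) == 2, all(shape >= 24), cortex_width >= 1)
  nr <- shape[1]; nc <- shape[2]

  # elliptical footprint with a thin inner cortical band
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  a <- 0.42 * nr; b <- 0.45 * nc
  row <- matrix(seq_len(nr) - 1, nr, nc)
  col <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  rad2 <- ((row - cy) / a)^2 + ((col - cx) / b)^2
  embryo_mask <- rad2 <= 1
  # inner ellipse shrunk by cortex_width (in pixels, along both axes)
  inner <- ((row - cy) / (a - cortex_width))^2 +
    ((col - cx) / (b - cortex_width))^2
  cortex_mask <- embryo_mask & inner > 1
  if (!any(cortex_mask)) abort("degenerate scene: empty cortex mask")

  # SDR box centred on the anterior (left) pole of the cortex
  anterior_col <- min(col[cortex_mask])
  r_mid <- round(stats::median(row[cortex_mask & col <= anterior_col + 2]))
  r0 <- max(0, r_mid - sdr_size[1] %/% 2)
  c0 <- max(0, anterior_col - 1)
  sdr_box <- as.integer(c(r0, min(nr, r0 + sdr_size[1]),
                          c0, min(nc, c0 + sdr_size[2])))

  f_base <- fret_to_force(e_base, params)
  f_sdr <- fret_to_force(e_sdr, params)
  force_field <- matrix(0, nr, nc)
  force_field[embryo_mask] <- f_base
  in_box <- box_mask(sdr_box, c(nr, nc))
  force_field[embryo_mask & in_box] <- f_sdr

  structure(
    list(shape = as.integer(shape), embryo_mask = embryo_mask,
         cortex_mask = cortex_mask, force_field = force_field,
         sdr_box = sdr_box, construct = construct, seed = as.integer(seed)),
    class = "tension_scene"
  )
}

#' Logical mask for a half-open pixel box
#'
#' @param box Integer vector `c(row0, row1, col0, col1)`, 0-based, half-open.
#' @param shape `c(rows, cols)` of the target grid.
#' @return Logical matrix, `TRUE` inside the box.
#' @export
box_mask <- function(box, shape) {
  stopifnot(length(box) == 4, box[2] > box[1], box[4] > box[3])
  m <- matrix(FALSE, shape[1], shape[2])
  rows <- seq.int(box[1] + 1L, min(box[2], shape[1]))
  cols <- seq.int(box[3] + 1L, min(box[4], shape[2]))
  m[rows, cols] <- TRUE
  m
}

#' Ground-truth efficiency map implied by a scene
#'
#' Force-sensitive constructs map the tension field through
#' [force_to_fret()]; control constructs are force-insensitive and give a
#' spatially constant efficiency (`e0` for the terminal fusion, the high/low
#' control values for the rigid-linker and separator constructs).
#'
#' @inheritParams simulate_fret_stack
#' @return Numeric matrix of per-pixel efficiencies (defined on the full
#'   grid; only sensor-bearing pixels are ever imaged).
#' @export
scene_truth_e <- function(scene, params = forward_model_params()) {
  switch(scene$construct,
    "TSMod" = force_to_fret(scene$force_field, params),
    "N-TSMod" = matrix(params$e0, scene$shape[1], scene$shape[2]),
    "5aa" = matrix(params$e_high, scene$shape[1], scene$shape[2]),
    "TRAF" = matrix(params$e_low, scene$shape[1], scene$shape[2])
  )
}
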