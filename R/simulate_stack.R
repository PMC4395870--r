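#' Three-channel imaging stack container
#'
#' Holds the per-pixel intensities of the three acquired channels across
#' z-frames plus the per-channel background estimates. Channels are stored as
#' `rows x cols x n_frames` numeric arrays.
#'
#' @param ID,IA,IF Numeric arrays (or matrices for a single frame) with
#'   identical dimensions: donor emission under donor excitation, acceptor
#'   emission under acceptor excitation, and acceptor emission under donor
#'   excitation (raw FRET channel).
#' @param background Named numeric vector `c(ID = , IA = , IF = )` of scalar
#'   background estimates in counts, or a single scalar used for all three.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(ID, IA, IF, background = c(ID = 0, IA = 0, IF = 0)) {
  as_arr <- function(x) if (length(dim(x)) == 2) array(x, c(dim(x), 1L)) else x
  ID <- as_arr(ID); IA <- as_arr(IA); IF <- as_arr(IF)
  if (!identical(dim(ID), dim(IA)) || !identical(dim(ID), dim(IF))) {
    abort("all three channels must share identical dimensions per frame")
  }
  if (length(dim(ID)) != 3) abort("channels must be rows x cols x frames arrays")
  if (length(background) == 1) background <- c(ID = background, IA = background, IF = background)
  background <- background[c("ID", "IA", "IF")]
  if (anyNA(background)) abort("`background` must provide values for ID, IA and IF")
  structure(
    list(ID = ID, IA = IA, IF = IF,
         background = background, n_frames = dim(ID)[3]),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$ID)
  cat(sprintf("<channel_stack> %d x %d px, %d frame(s); background ID=%.3g IA=%.3g IF=%.3g\n",
              d[1], d[2], d[3], x$background["ID"], x$background["IA"], x$background["IF"]))
  invisible(x)
}

#' Render a scene into a three-channel FRET imaging stack
#'
#' Applies the full forward model: the construct-dependent ground-truth
#' efficiency map ([scene_truth_e()]), a cortical sensor-density field with an
#' optional expression gradient, linear spectral mixing of the raw FRET
#' channel with donor and acceptor bleed-through, a constant background, and
#' (optionally) Poisson shot noise drawn independently per pixel, channel and
#' frame.
#'
#' For a pixel with excitation budget `S` and true efficiency `E` the
#' noiseless channel means are
#' \itemize{
#'   \item quenched donor `qD = S (1 - E) qd phi_d`, so `ID = qD + bg`;
#'   \item direct acceptor signal `Sa = S ia_gain` (FRET-independent),
#'     so `IA = Sa + bg`;
#'   \item sensitized emission `cF = S E phi_a`, so
#'     `IF = cF + delta qD + alpha Sa + bg`.
#' }
#' With this construction the bleed-through correction and index formula of
#' the analysis pipeline invert the model exactly:
#' `(cF qd phi_d/phi_a) / (qD + cF qd phi_d/phi_a) = E`.
#'
#' @param scene A [tension_scene()].
#' @param params A [forward_model_params()].
#' @param n_frames Number of z-frames to render (frames share the same
#'   geometry and differ only in their noise draws).
#' @param seed Integer seed; defaults to the scene's own seed. Identical
#'   seeds give bit-identical stacks.
#' @return A list of class `fret_sim` with elements `stack`
#'   ([channel_stack()]), `truth_e` (ground-truth efficiency matrix),
#'   `density` (excitation-budget matrix) and `scene`.
#' @examples
#' sim <- simulate_fret_stack(tension_scene(shape = c(48, 64)),
#'                            forward_model_params(noise = "none"))
#' range(sim$truth_e[sim$scene$cortex_mask])
#' @export
simulate_fret_stack <- function(scene,
                                params = forward_model_params(),
                                n_frames = 3,
                                seed = scene$seed) {
  stopifnot(inherits(scene, "tension_scene"), inherits(params, "forward_model_params"))
  if (!any(scene$cortex_mask)) abort("scene has an empty cortex mask: nothing to image")
  nr <- scene$shape[1]; nc <- scene$shape[2]

  truth_e <- scene_truth_e(scene, params)

  # sensor concentrates in the cortical band; optional expression gradient
  grad <- 1 + params$density_gradient *
    (2 * (matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) / (nc - 1)) - 1)
  density <- ifelse(scene$cortex_mask, params$sensor_density * grad, 0)

  # optional intermolecular contamination: a density-dependent extra transfer
  # channel that an intramolecular sensor does not have (truth_e reports the
  # linker efficiency only)
  e_emit <- truth_e + (1 - truth_e) *
    params$intermolecular * density / params$sensor_density
  qd_true <- density * (1 - e_emit) * params$qd * params$phi_d
  cf_true <- density * e_emit * params$phi_a
  ia_sig <- density * params$ia_gain
  bg <- params$background

  mu_id <- qd_true + bg
  mu_ia <- ia_sig + bg
  mu_if <- cf_true + params$delta * qd_true + params$alpha * ia_sig + bg
  if (max(mu_id, mu_ia, mu_if) > .Machine$integer.max) {
    abort("forward model overflows the count range; lower `sensor_density`")
  }

  draw <- function(mu) {
    a <- array(0, c(nr, nc, n_frames))
    for (k in seq_len(n_frames)) {
      a[, , k] <- if (params$noise == "poisson") rpois(length(mu), mu) else mu
    }
    a
  }
  stack <- withr::with_seed(seed, {
    channel_stack(draw(mu_id), draw(mu_ia), draw(mu_if),
                  background = c(ID = bg, IA = bg, IF = bg))
  })
  structure(list(stack = stack, truth_e = truth_e, density = density,
                 scene = scene, params = params, seed = as.integer(seed)),
            class = "fret_sim")
}
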