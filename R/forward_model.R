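#' Forward-model parameters for the synthetic tension-sensor imager
#'
#' Bundles every constant needed to turn a per-pixel tension field into the
#' three acquired channels of an intensity-based FRET experiment: donor
#' emission under donor excitation (`ID`), acceptor emission under acceptor
#' excitation (`IA`) and sensitized acceptor emission under donor excitation
#' (`IF`, the raw FRET channel).
#'
#' The sensor is an intramolecular tension-sensor module: donor and acceptor
#' joined by an elastic linker, so stretching increases the fluorophore
#' separation `r` and lowers the transfer efficiency
#' `E = 1 / (1 + (r / R0)^6)`. The linker is modelled as a linear entropic
#' spring, `r(f) = r0 + f / spring_constant`. The acceptor quantum yield is
#' folded into the acceptor collection efficiency `phi_a`, so that the
#' sensitized-emission index formula used by [compute_fret_index()] is the
#' exact algebraic inverse of this generator.
#'
#' @param e0 Zero-force FRET efficiency (0 < e0 < 1). The zero-force
#'   separation is derived from it as `r0 = R0 * ((1 - e0) / e0)^(1/6)`.
#' @param r0 Zero-force fluorophore separation in nm; overrides `e0` if given.
#' @param R0 Foerster radius in nm.
#' @param spring_constant Tension (arbitrary force units) per nm of extension.
#' @param sensor_density Mean donor excitations per cortical pixel per frame
#'   (sets the photon budget and hence the shot-noise level).
#' @param density_gradient Relative amplitude of a linear left-to-right
#'   expression gradient across the embryo (0 = uniform). Used to verify that
#'   the FRET index is independent of expression level.
#' @param qd Donor quantum yield.
#' @param phi_d,phi_a Donor and acceptor collection efficiencies (the acceptor
#'   quantum yield is folded into `phi_a`). The calibration ratio
#'   phiD/phiA is `phi_d / phi_a`.
#' @param ia_gain Directly excited acceptor signal per sensor excitation
#'   budget unit (FRET-independent; feeds the `IA` channel only).
#' @param alpha,delta Acceptor and donor spectral bleed-through fractions
#'   contaminating the raw FRET channel.
#' @param background Background level in counts, added to every channel.
#' @param noise `"none"` for noiseless expectation images, `"poisson"` for
#'   shot noise (each channel drawn from a Poisson law with the noiseless
#'   value as mean).
#' @param intermolecular Strength of a contaminating intermolecular transfer
#'   term: the fraction of remaining donor excitation transferred to
#'   unlinked acceptors at nominal sensor density (scales linearly with
#'   local density). Zero for a pure intramolecular sensor; positive values
#'   exist to verify that the expression-independence check detects the
#'   contamination.
#' @param e_high,e_low Fixed efficiencies of the force-insensitive high-FRET
#'   (short rigid linker) and low-FRET (long separator) control constructs.
#'   The no-force terminal fusion control uses `e0`. These are configuration
#'   values, not measured constants.
#'
#' @return An object of class `forward_model_params` (a named list).
#' @seealso [force_to_fret()], [tension_scene()], [simulate_fret_stack()]
#' @export
forward_model_params <- function(e0 = 0.45,
                                 r0 = NULL,
                                 R0 = 5.4,
                                 spring_constant = 1,
                                 sensor_density = 500,
                                 density_gradient = 0.3,
                                 qd = 0.6,
                                 phi_d = 0.54,
                                 phi_a = 0.45,
                                 ia_gain = 0.5,
                                 alpha = 0.1,
                                 delta = 0.15,
                                 background = 20,
                                 noise = c("poisson", "none"),
                                 intermolecular = 0,
                                 e_high = 0.55,
                                 e_low = 0.15) {
  noise <- match.arg(noise)
  if (is.null(r0)) {
    stopifnot(is.numeric(e0), length(e0) == 1, e0 > 0, e0 < 1)
    r0 <- R0 * ((1 - e0) / e0)^(1 / 6)
  } else {
    e0 <- 1 / (1 + (r0 / R0)^6)
  }
  for (nm in c("alpha", "delta")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1) {
      abort(sprintf("`%s` must be a fraction in [0, 1)", nm))
    }
  }
  stopifnot(
    qd > 0, qd <= 1, phi_d > 0, phi_a > 0, ia_gain > 0,
    spring_constant > 0, sensor_density > 0, background >= 0,
    density_gradient >= 0, density_gradient < 1,
    intermolecular >= 0, intermolecular < 1,
    e_high > 0, e_high < 1, e_low > 0, e_low < 1
  )
  structure(
    list(
      e0 = e0, r0 = r0, R0 = R0, spring_constant = spring_constant,
      sensor_density = sensor_density, density_gradient = density_gradient,
      qd = qd, phi_d = phi_d, phi_a = phi_a, ia_gain = ia_gain,
      alpha = alpha, delta = delta, background = background, noise = noise,
      intermolecular = intermolecular, e_high = e_high, e_low = e_low
    ),
    class = "forward_model_params"
  )
}

#' Map tension to FRET efficiency (and back)
#'
#' `force_to_fret()` evaluates the forward model
#' `E(f) = 1 / (1 + (r(f) / R0)^6)` with the linear-spring extension
#' `r(f) = r0 + f / spring_constant`; it is strictly decreasing in `f` and
#' equals the zero-force efficiency at `f = 0`. `fret_to_force()` is its
#' exact inverse and is the convenient way to build scenes with prescribed
#' ground-truth efficiencies.
#'
#' @param force Non-negative tension value(s), arbitrary force units.
#' @param params A [forward_model_params()] object.
#' @return FRET efficiency in (0, 1), same shape as `force`.
#' @examples
#' p <- forward_model_params(e0 = 0.45)
#' force_to_fret(0, p)            # = 0.45
#' fret_to_force(0.2, p)          # tension that yields E = 0.2
#' @export
force_to_fret <- function(force, params = forward_model_params()) {
  if (any(force < 0, na.rm = TRUE)) {
    abort("`force` must be non-negative: the linker cannot be compressed below its zero-force length")
  }
  r <- params$r0 + force / params$spring_constant
  1 / (1 + (r / params$R0)^6)
}

#' @rdname force_to_fret
#' @param efficiency FRET efficiency value(s) in (0, 1), not exceeding the
#'   zero-force efficiency (tension can only lower FRET).
#' @export
fret_to_force <- function(efficiency, params = forward_model_params()) {
  stopifnot(all(efficiency > 0), all(efficiency < 1))
  if (any(efficiency > params$e0 + 1e-12)) {
    abort("`efficiency` above the zero-force value is unreachable under tension")
  }
  r <- params$R0 * ((1 - efficiency) / efficiency)^(1 / 6)
  pmax(0, (r - params$r0) * params$spring_constant)
}
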