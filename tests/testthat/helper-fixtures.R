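# shared small fixtures, built in code at test time

small_scene <- function(seed = 1, construct = "TSMod",
                        params = forward_model_params()) {
  tension_scene(shape = c(48, 64), construct = construct,
                params = params, seed = seed)
}

noiseless_params <- function(...) {
  forward_model_params(noise = "none", ...)
}

# noiseless channel means for one pixel with excitation budget S and true
# efficiency E, per the documented forward model (used as an independent
# reference for single-pixel checks)
pixel_means <- function(S, E, p) {
  qd_true <- S * (1 - E) * p$qd * p$phi_d
  ia_sig <- S * p$ia_gain
  cf_true <- S * E * p$phi_a
  c(ID = qd_true + p$background,
    IA = ia_sig + p$background,
    IF = cf_true + p$delta * qd_true + p$alpha * ia_sig + p$background)
}

one_pixel_stack <- function(means, background) {
  channel_stack(matrix(means["ID"]), matrix(means["IA"]), matrix(means["IF"]),
                background = c(ID = background, IA = background, IF = background))
}
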