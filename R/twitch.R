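#' Active twitch force
#'
#' Single-twitch force waveform: a difference of exponentials with rise time
#' constant solved from `time_to_peak` and decay constant `relaxation_tau`,
#' normalised so that the peak equals `peak_twitch_force` at optimal length
#' (`length_fraction = 1`) and the 60 bpm reference rate. The peak scales
#' with the active length-tension factor and the force-frequency factor.
#'
#' @param t_since_activation Time since activation, ms (vectorised).
#' @param tissue A [tissue_params()].
#' @param length_fraction Length as a fraction of `L_max`.
#' @param rate Pacing rate, bpm (used for the force-frequency factor).
#' @return Force, mN; 0 at `t = 0` and decaying back to 0.
#' @export
#' @examples
#' tp <- tissue_params()
#' active_force(tp$time_to_peak, tp) # = peak_twitch_force
active_force <- function(t_since_activation, tissue, length_fraction = 1,
                         rate = 60) {
  if (any(t_since_activation < 0)) {
    abort_domain("`t_since_activation` must be non-negative")
  }
  amp <- tissue$peak_twitch_force *
    active_length_factor(tissue, length_fraction) *
    ffr_factor(rate, tissue$ffr)
  amp * twitch_shape(t_since_activation, tissue)
}

# unit-peak difference-of-exponentials twitch shape
twitch_shape <- function(t_ms, tissue) {
  td <- tissue$relaxation_tau
  tr <- tissue$rise_tau
  peak <- exp(-tissue$time_to_peak / td) - exp(-tissue$time_to_peak / tr)
  (exp(-t_ms / td) - exp(-t_ms / tr)) / peak
}

#' Excitation test for a stimulus event
#'
#' A stimulus excites the tissue iff its charge reaches the threshold charge
#' (constant-charge strength-duration relation: `threshold_current` mA at
#' 1 ms pulse width) and the tissue is no longer refractory, i.e. the time
#' since the last activation strictly exceeds the refractory period. A
#' successful activation updates `last_activation_time`.
#'
#' @param tissue A [tissue_params()].
#' @param state A [chamber_state()].
#' @param t Stimulus time, s.
#' @param stimulus_current Pulse amplitude, mA.
#' @param pulse_width Charging-phase width, ms.
#' @return A list with `activated` (flag), the updated `state`, and
#'   `interval_ms` (time since the previous activation).
#' @export
excitable <- function(tissue, state, t, stimulus_current, pulse_width = 1) {
  interval_ms <- (t - state$last_activation_time) * 1000
  charge_ok <- stimulus_current * pulse_width >= tissue$threshold_current * 1
  # a stimulus at an interval exactly equal to the refractory period fails;
  # the epsilon keeps that boundary stable against floating-point jitter in
  # schedule times
  refractory_ok <- interval_ms > tissue$refractory_period + 1e-6
  activated <- isTRUE(charge_ok && refractory_ok)
  if (activated) {
    state$last_activation_time <- t
  }
  state$time <- t
  list(activated = activated, state = state, interval_ms = interval_ms)
}

# Relative amplitude of a beat elicited `interval_ms` after the previous
# activation. Beats just past the refractory period are attenuated
# (premature-beat attenuation) and recover towards full amplitude with the
# restitution time constant; the floor keeps even the earliest propagated
# beat clearly distinct from noise.
restitution_factor <- function(interval_ms, tissue) {
  rp <- tissue$refractory_period
  fl <- tissue$restitution$floor
  tau <- tissue$restitution$tau
  ifelse(is.finite(interval_ms),
         fl + (1 - fl) * (1 - exp(-pmax(interval_ms - rp, 0) / tau)),
         1)
}
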