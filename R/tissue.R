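#' Slice geometry
#'
#' Physical dimensions of the mounted tissue slice. The muscle span between
#' the two fixation points (`length`) sets the operating length of the
#' preparation; `width * thickness` is the cross-section through which all
#' wall-stress values are computed. The default 5 x 5 x 0.3 mm corresponds
#' to a typical vibratome slice trimmed for chamber mounting.
#'
#' @param length Muscle span between fixations, mm.
#' @param width Slice width, mm.
#' @param thickness Slice thickness, mm.
#'
#' @return An object of class `slice_geometry` with fields `length`, `width`,
#'   `thickness` and the derived `cross_section` (mm^2).
#' @export
#' @examples
#' g <- slice_geometry()
#' g$cross_section # 1.5 mm^2
slice_geometry <- function(length = 5, width = 5, thickness = 0.3) {
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(thickness, "thickness")
  structure(
    list(length = length, width = width, thickness = thickness,
         cross_section = width * thickness),
    class = "slice_geometry"
  )
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat(sprintf("<slice_geometry> %g x %g x %g mm (cross-section %g mm^2)\n",
              x$length, x$width, x$thickness, x$cross_section))
  invisible(x)
}

# Active length-tension factor: smooth concave curve in the length fraction
# lambda = L / L_max, equal to 1 at lambda = 1 and falling off quadratically
# with half-width `width`. Clamped at zero so active force is never negative.
length_tension_params <- function(width = 0.5) {
  check_positive(width, "width")
  list(width = width)
}

# Passive (diastolic) stiffness: exponential strain curve
#   P(lambda) = scale * (exp(beta * (lambda - lambda_slack)) - 1), lambda > slack
# `scale` is calibrated at construction so that P(preload_fraction) equals
# `preload_at_fraction` mN: the standard 1 mN preload then sits at 83% of the
# length of maximal active force.
passive_stiffness_params <- function(beta = 15, lambda_slack = 0.70,
                                     preload_at_fraction = 1,
                                     preload_fraction = 0.83) {
  check_positive(beta, "beta")
  if (lambda_slack <= 0 || lambda_slack >= preload_fraction) {
    abort_domain("`lambda_slack` must lie in (0, preload_fraction)")
  }
  scale <- preload_at_fraction / expm1(beta * (preload_fraction - lambda_slack))
  list(beta = beta, lambda_slack = lambda_slack, scale = scale,
       preload_fraction = preload_fraction)
}

#' Force-frequency parameter sets
#'
#' Piecewise-linear twitch-force factor versus pacing rate, normalised to 1
#' at 60 bpm. The `"cultured"` set gains force at bradycardia (an adaptation
#' to sustained 0.2 Hz pacing) while both sets lose force as rate rises from
#' 60 to 180 bpm; the `"fresh"` set is flat-to-slightly-positive below
#' 60 bpm.
#'
#' @param set `"cultured"` or `"fresh"`.
#' @return A list with vectors `rate_bpm` and `factor`.
#' @export
ffr_params <- function(set = c("cultured", "fresh")) {
  set <- match.arg(set)
  if (set == "cultured") {
    list(set = set, rate_bpm = c(12, 30, 60, 120, 180),
         factor = c(1.35, 1.15, 1.00, 0.85, 0.70))
  } else {
    list(set = set, rate_bpm = c(12, 30, 60, 120, 180),
         factor = c(0.95, 0.98, 1.00, 0.85, 0.70))
  }
}

ffr_factor <- function(rate_bpm, ffr) {
  approx(ffr$rate_bpm, ffr$factor, xout = rate_bpm, rule = 2)$y
}

# Solve the rise time constant of the difference-of-exponentials twitch so
# that its peak occurs at `time_to_peak`. The peak time increases from 0 to
# relaxation_tau as tau_rise approaches relaxation_tau from below, so a
# solution exists iff time_to_peak < relaxation_tau.
solve_rise_tau <- function(time_to_peak, relaxation_tau) {
  if (time_to_peak >= relaxation_tau) {
    abort_domain("`time_to_peak` must be smaller than `relaxation_tau` for the difference-of-exponentials twitch")
  }
  peak_time <- function(tr) {
    td <- relaxation_tau
    log(td / tr) * td * tr / (td - tr)
  }
  uniroot(function(tr) peak_time(tr) - time_to_peak,
          interval = c(relaxation_tau * 1e-6, relaxation_tau * (1 - 1e-9)),
          tol = 1e-10)$root
}

#' Tissue parameters of the simulated slice
#'
#' Ground-truth contractile, excitability and load-dependence state of the
#' digital slice. All analysis-chain validation works by configuring these
#' parameters, simulating raw sensor traces, and checking that the analysis
#' recovers them.
#'
#' @param geometry A [slice_geometry()].
#' @param peak_twitch_force Active twitch force at optimal length and the
#'   60 bpm reference rate, mN.
#' @param time_to_peak Time from activation to peak force, ms.
#' @param relaxation_tau Relaxation time constant of the twitch decay, ms.
#' @param refractory_period Refractory period, ms; a stimulus arriving at or
#'   before this interval after the last activation fails to excite.
#' @param threshold_current Excitation threshold at 1 ms pulse width, mA
#'   (strength-duration handled as constant threshold charge).
#' @param length_tension Active length-tension parameters
#'   ([length_tension_params()]).
#' @param passive_stiffness Passive strain-curve parameters
#'   ([passive_stiffness_params()]).
#' @param ffr Force-frequency parameters ([ffr_params()]).
#' @param restitution Premature-beat restitution: list with `floor`
#'   (relative amplitude of a beat elicited just beyond the refractory
#'   period; premature beats are visibly attenuated but remain clearly
#'   distinct from noise) and `tau` (ms recovery constant towards full
#'   amplitude).
#'
#' @return An object of class `tissue_params`. The derived fields `rise_tau`
#'   (ms) and `l_max` (mm, length of maximal active force) are precomputed.
#' @export
#' @examples
#' tp <- tissue_params()
#' tp$refractory_period # 425 ms baseline
tissue_params <- function(geometry = slice_geometry(),
                          peak_twitch_force = 6,
                          time_to_peak = 150,
                          relaxation_tau = 200,
                          refractory_period = 425,
                          threshold_current = 20,
                          length_tension = length_tension_params(),
                          passive_stiffness = passive_stiffness_params(),
                          ffr = ffr_params("cultured"),
                          restitution = list(floor = 0.4, tau = 300)) {
  stopifnot(inherits(geometry, "slice_geometry"))
  check_positive(peak_twitch_force, "peak_twitch_force")
  check_positive(refractory_period, "refractory_period")
  if (threshold_current <= 0 || threshold_current > 75) {
    abort_domain("`threshold_current` must lie in (0, 75] mA")
  }
  rise_tau <- solve_rise_tau(time_to_peak, relaxation_tau)
  structure(
    list(geometry = geometry,
         peak_twitch_force = peak_twitch_force,
         time_to_peak = time_to_peak,
         relaxation_tau = relaxation_tau,
         rise_tau = rise_tau,
         refractory_period = refractory_period,
         threshold_current = threshold_current,
         length_tension = length_tension,
         passive_stiffness = passive_stiffness,
         ffr = ffr,
         restitution = restitution,
         # the mounted span (geometry$length) is by calibration the length at
         # which the standard preload sits, i.e. preload_fraction of L_max
         l_max = geometry$length / passive_stiffness$preload_fraction),
    class = "tissue_params"
  )
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<tissue_params>\n",
    "  peak twitch force : %g mN (ttp %g ms, tau %g ms)\n",
    "  refractory period : %g ms\n",
    "  threshold current : %g mA at 1 ms\n",
    "  L_max             : %.3f mm (span %g mm = %g%% of L_max)\n"),
    x$peak_twitch_force, x$time_to_peak, x$relaxation_tau,
    x$refractory_period, x$threshold_current, x$l_max, x$geometry$length,
    100 * x$passive_stiffness$preload_fraction))
  invisible(x)
}

#' Passive (diastolic) force at a given length fraction
#'
#' @param tissue A [tissue_params()].
#' @param length_fraction Length as a fraction of `L_max`.
#' @return Passive force, mN (0 below the slack length).
#' @export
passive_force <- function(tissue, length_fraction) {
  ps <- tissue$passive_stiffness
  ifelse(length_fraction > ps$lambda_slack,
         ps$scale * expm1(ps$beta * (length_fraction - ps$lambda_slack)),
         0)
}

# Active length-tension scaling in [0, 1]
active_length_factor <- function(tissue, length_fraction) {
  w <- tissue$length_tension$width
  pmax(0, 1 - ((1 - length_fraction) / w)^2)
}

#' Chamber state
#'
#' Mutable state of one culture chamber: the imposed diastolic preload, the
#' manual linear-drive offset that stretches the tissue, and the excitation
#' bookkeeping used by [excitable()].
#'
#' @param preload Diastolic force, mN.
#' @param drive_position Linear-drive offset from the nominal mounting
#'   position, mm (positive stretches the tissue).
#' @param time Current chamber time, s.
#' @param last_activation_time Time of the last successful excitation, s.
#' @return An object of class `chamber_state`.
#' @export
chamber_state <- function(preload = 1, drive_position = 0, time = 0,
                          last_activation_time = -Inf) {
  check_nonnegative(preload, "preload")
  structure(
    list(preload = preload, drive_position = drive_position, time = time,
         last_activation_time = last_activation_time),
    class = "chamber_state"
  )
}

# Length fraction lambda = L / L_max at the current drive position
operating_fraction <- function(state, tissue) {
  (tissue$geometry$length + state$drive_position) / tissue$l_max
}

#' Adjust the linear drive to a target preload
#'
#' Emulates the manual preload adjustment performed after mounting and again
#' after 24 h of culture: the drive is moved until the diastolic (passive)
#' force is within `tol` of `target`.
#'
#' @param state A [chamber_state()].
#' @param tissue A [tissue_params()].
#' @param target Target diastolic force, mN.
#' @param tol Acceptance tolerance, mN.
#' @param drive_range Reachable drive offsets, mm.
#' @return The updated `chamber_state` (fields `preload`, `drive_position`).
#' @export
#' @examples
#' st <- adjust_preload(chamber_state(), tissue_params(), target = 1)
#' st$drive_position # ~0: the default span is calibrated to 1 mN
adjust_preload <- function(state, tissue, target = 1, tol = 0.01,
                           drive_range = c(-2, 3)) {
  check_nonnegative(target, "target")
  lam <- function(d) (tissue$geometry$length + d) / tissue$l_max
  f <- function(d) passive_force(tissue, lam(d)) - target
  if (target < tol) {
    # slack: park the drive at the slack length, zero diastolic force
    d0 <- tissue$passive_stiffness$lambda_slack * tissue$l_max -
      tissue$geometry$length
    d0 <- max(d0, drive_range[1])
    state$drive_position <- d0
    state$preload <- passive_force(tissue, lam(d0))
    return(state)
  }
  if (f(drive_range[2]) < 0) {
    abort_limit("target preload unreachable within the drive range")
  }
  if (f(drive_range[1]) > 0) {
    abort_limit("tissue still above target preload at minimum drive position")
  }
  d <- uniroot(f, interval = drive_range, tol = 1e-9)$root
  state$drive_position <- d
  state$preload <- passive_force(tissue, lam(d))
  stopifnot(abs(state$preload - target) <= tol)
  state
}
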