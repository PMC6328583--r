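#' Spring/magnet/sensor transducer
#'
#' Calibration constants of the elastic force transducer: the tissue pulls
#' on a steel spring wire (Hooke constant `spring_constant`), the magnetic
#' tip of the wire moves with the fixation point, and a magnetic field
#' sensor converts tip displacement to flux with sensitivity `sensitivity`.
#' The sensor operating point produces at most `baseline_flux` at rest, and
#' its signal-to-noise ratio corresponds to a single-sample displacement
#' resolution of `resolution` (interpreted as one standard deviation, so
#' the per-sample flux noise is `sensitivity * resolution`).
#'
#' @param spring_constant Spring constant, mN/mm.
#' @param sensitivity Flux change per tip displacement, T/m.
#' @param baseline_flux Flux at the rest position, T (at most 1.2 mT).
#' @param resolution Single-sample displacement resolution (1 SD), um.
#' @return An object of class `spring_transducer` with the derived
#'   `noise_sd` in T.
#' @export
#' @examples
#' tr <- spring_transducer()
#' tr$noise_sd # 3.5e-6 T = 7 T/m x 0.5 um
spring_transducer <- function(spring_constant = 75, sensitivity = 7,
                              baseline_flux = 1.2e-3, resolution = 0.5) {
  check_positive(spring_constant, "spring_constant")
  check_positive(sensitivity, "sensitivity")
  check_positive(resolution, "resolution")
  if (abs(baseline_flux) > 1.2e-3 + 1e-12) {
    abort_domain("`baseline_flux` must not exceed the 1.2 mT operating budget")
  }
  structure(
    list(spring_constant = spring_constant, sensitivity = sensitivity,
         baseline_flux = baseline_flux, resolution = resolution,
         noise_sd = sensitivity * resolution * 1e-6),
    class = "spring_transducer"
  )
}

#' @export
print.spring_transducer <- function(x, ...) {
  cat(sprintf(
    "<spring_transducer> k = %g mN/mm, s = %g T/m, baseline %g mT, noise %g uT\n",
    x$spring_constant, x$sensitivity, x$baseline_flux * 1e3,
    x$noise_sd * 1e6))
  invisible(x)
}

#' Force to spring-tip displacement
#'
#' Hooke's law on the spring wire: `x = F / k`.
#'
#' @param force Force, mN (non-negative).
#' @param transducer A [spring_transducer()].
#' @return Displacement, mm.
#' @export
#' @examples
#' force_to_displacement(22.5) # 0.3 mm = 6% of a 5 mm span
force_to_displacement <- function(force, transducer = spring_transducer()) {
  if (any(force < 0)) abort_domain("`force` must be non-negative")
  force / transducer$spring_constant
}

#' Displacement to magnetic-flux change
#'
#' Affine sensor model around the operating point: `dB = sensitivity * x`.
#' Displacements whose flux change exceeds the 1.2 mT operating budget
#' trigger a saturation warning but are not clipped.
#'
#' @param x Displacement, mm.
#' @param transducer A [spring_transducer()].
#' @return Flux change, T.
#' @export
displacement_to_flux <- function(x, transducer = spring_transducer()) {
  db <- transducer$sensitivity * x * 1e-3 # mm -> m
  if (any(abs(db) > 1.2e-3)) {
    warn("flux excursion beyond the 1.2 mT operating budget; affine sensor model extrapolated",
         class = "myoslice_saturation_warning")
  }
  db
}

#' Recover the force series from a raw trace
#'
#' Inverts the simulation path: `force = k * (B - baseline) / sensitivity`.
#' The calibration is taken from the trace attributes (as written by
#' [simulate_run()] and preserved by [read_trace()]/[write_trace()]) unless
#' a transducer is given explicitly.
#'
#' @param trace A trace tibble with columns `time` and `flux`.
#' @param transducer Optional [spring_transducer()] overriding the trace
#'   calibration.
#' @return The trace tibble with an added `force` column (mN).
#' @export
trace_to_force <- function(trace, transducer = NULL) {
  if (is.null(transducer)) transducer <- attr(trace, "transducer")
  if (is.null(transducer)) {
    abort_format("trace carries no calibration metadata and no transducer was supplied")
  }
  x_mm <- (trace$flux - transducer$baseline_flux) / transducer$sensitivity * 1e3
  trace$force <- transducer$spring_constant * x_mm
  trace
}
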