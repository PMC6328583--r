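#' Wall stress of a slice force
#'
#' Converts force to wall stress over the slice cross-section. With mN and
#' mm^2 the numeric value is directly in kN/m^2 (= kPa): the 22.5 mN force
#' reached at 6% shortening of the standard slice corresponds to the normal
#' systolic left-ventricular wall tension of 15 kN/m^2, and the 1 mN
#' preload to the normal mean diastolic wall stress of 0.66-0.67 kN/m^2.
#'
#' @param force Force, mN (vectorised).
#' @param geometry A [slice_geometry()].
#' @return Stress, kN/m^2.
#' @export
#' @examples
#' wall_stress(22.5) # 15
#' wall_stress(1)    # 0.667
wall_stress <- function(force, geometry = slice_geometry()) {
  stopifnot(inherits(geometry, "slice_geometry"))
  force / geometry$cross_section
}

#' Systolic design-point check
#'
#' Stress produced when the slice shortens by `shortening_fraction` of its
#' span against the spring: force is `k * s * length` (Hooke), stress that
#' force over the cross-section. The chamber design targets 15 kN/m^2 at 6%
#' shortening on the 75 mN/mm spring.
#'
#' @param spring_constant Spring constant, mN/mm.
#' @param shortening_fraction Shortening as a fraction of the span.
#' @param geometry A [slice_geometry()].
#' @return Stress, kN/m^2.
#' @export
#' @examples
#' systolic_design_check() # 15
systolic_design_check <- function(spring_constant = 75,
                                  shortening_fraction = 0.06,
                                  geometry = slice_geometry()) {
  check_positive(spring_constant, "spring_constant")
  check_nonnegative(shortening_fraction, "shortening_fraction")
  force <- spring_constant * shortening_fraction * geometry$length
  wall_stress(force, geometry)
}

#' Length-tension curve analysis
#'
#' Locates the stretch of maximal active twitch force (a quadratic is
#' fitted around the empirical maximum to interpolate between stretch
#' levels) and reports the length fraction, relative to that optimum, at
#' which the passive force crosses the preload (1 mN by default). For
#' tissue at the standard culture preload this fraction is about 0.83.
#'
#' @param data A data frame with columns `stretch` (absolute muscle length,
#'   mm), `active` (twitch amplitude, mN) and `passive` (diastolic force,
#'   mN), one row per stretch level.
#' @param preload Preload at which the length fraction is evaluated, mN.
#' @return A tibble with `l_max` (length of maximal active force, mm),
#'   `max_active` (mN), `length_at_preload` (mm), `fraction_at_preload`
#'   and `degenerate` (flag: flat active curve, no interior maximum).
#' @export
length_tension_analysis <- function(data, preload = 1) {
  stopifnot(all(c("stretch", "active", "passive") %in% names(data)))
  data <- dplyr::arrange(data, .data$stretch)
  if (diff(range(data$active)) < 1e-9 * max(abs(data$active), 1)) {
    return(tibble(l_max = NA_real_, max_active = max(data$active),
                  length_at_preload = NA_real_,
                  fraction_at_preload = NA_real_, degenerate = TRUE))
  }
  i <- which.max(data$active)
  if (i == 1 || i == nrow(data)) {
    l_max <- data$stretch[i]
    max_active <- data$active[i]
  } else {
    # quadratic through the maximum and its neighbours
    idx <- (i - 1):(i + 1)
    fit <- lm(active ~ stretch + I(stretch^2), data = data[idx, ])
    b <- coef(fit)
    l_max <- -b[["stretch"]] / (2 * b[["I(stretch^2)"]])
    max_active <- unname(predict(fit, tibble(stretch = l_max)))
  }
  # monotone passive curve: invert by interpolation
  ok <- !duplicated(data$passive)
  length_at_preload <- approx(data$passive[ok], data$stretch[ok],
                              xout = preload)$y
  tibble(l_max = unname(l_max), max_active = unname(max_active),
         length_at_preload = length_at_preload,
         fraction_at_preload = length_at_preload / l_max,
         degenerate = FALSE)
}

#' Length-tension sweep on the digital slice
#'
#' Generates the stretch-response data that [length_tension_analysis()]
#' consumes, by evaluating the twin's passive curve and active twitch
#' amplitude over a grid of muscle lengths.
#'
#' @param tissue A [tissue_params()].
#' @param stretches Absolute muscle lengths, mm; the default grid spans 75%
#'   to 110% of the optimum so that the maximum lies inside the sweep.
#' @param rate Pacing rate for the force-frequency factor, bpm.
#' @return A tibble with `stretch`, `active`, `passive`.
#' @export
sweep_length_tension <- function(tissue,
                                 stretches = seq(0.75, 1.1, by = 0.01) *
                                   tissue$l_max,
                                 rate = 12) {
  lambda <- stretches / tissue$l_max
  tibble(
    stretch = stretches,
    active = tissue$peak_twitch_force *
      active_length_factor(tissue, lambda) * ffr_factor(rate, tissue$ffr),
    passive = passive_force(tissue, lambda)
  )
}

#' Force-frequency analysis
#'
#' Normalises twitch amplitudes to the 60 bpm reference and classifies the
#' force-frequency relation from the segment slopes: `positive` (force
#' rises with rate), `negative`, or `biphasic` (sign change). A gain of
#' normalised force below 60 bpm - the hallmark of tissue adapted to
#' bradycardic culture pacing - is flagged separately.
#'
#' @param data A data frame with columns `rate` (bpm) and `amplitude` (mN).
#' @return A list with `curve` (tibble: `rate`, `amplitude`, `normalized`),
#'   `classification`, and `bradycardia_gain` (flag).
#' @export
ffr_analysis <- function(data) {
  stopifnot(all(c("rate", "amplitude") %in% names(data)))
  if (nrow(data) < 2) {
    abort_domain("need at least two pacing rates for a force-frequency curve")
  }
  data <- dplyr::arrange(data, .data$rate)
  ref <- approx(data$rate, data$amplitude, xout = 60, rule = 2)$y
  curve <- tibble(rate = data$rate, amplitude = data$amplitude,
                  normalized = data$amplitude / ref)
  slopes <- diff(curve$normalized) / diff(curve$rate)
  classification <- if (all(slopes >= 0)) "positive"
    else if (all(slopes <= 0)) "negative" else "biphasic"
  bradycardia_gain <- any(curve$normalized[curve$rate < 60] > 1 + 1e-9)
  list(curve = curve, classification = classification,
       bradycardia_gain = bradycardia_gain)
}
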