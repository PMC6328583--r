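#' Detect twitches in a calibrated force series
#'
#' Stimulus-aligned peak detection: for every regular stimulus in the
#' schedule the diastolic baseline is taken as the median force over the
#' 250 ms preceding the stimulus, the peak as the maximum force between the
#' stimulus and the next regular stimulus (capped at `max_window` s), and
#' the twitch amplitude as peak minus baseline. Stimuli that did not elicit
#' a contraction (amplitude below `min_amplitude`) yield no event.
#'
#' @param trace A trace tibble; either a raw `myo_trace` (converted with
#'   [trace_to_force()]) or any tibble with `time` and `force` columns.
#' @param schedule The stimulus schedule used during acquisition.
#' @param baseline_window Pre-stimulus baseline window, s.
#' @param max_window Maximum search window after the stimulus, s.
#' @param min_amplitude Minimum amplitude for an event to count, mN.
#' @return A tibble of twitch events: `stimulus_time`, `onset`, `peak_time`,
#'   `peak_force`, `diastolic_force`, `amplitude`.
#' @export
#' @examples
#' tr <- simulate_run(tissue_params(), pacing_schedule(0.2, 30),
#'                    run_config(duration = 30, seed = 1))
#' detect_twitches(tr, pacing_schedule(0.2, 30))
detect_twitches <- function(trace, schedule, baseline_window = 0.25,
                            max_window = 2.5, min_amplitude = 0.2) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    return(tibble(stimulus_time = numeric(), onset = numeric(),
                  peak_time = numeric(), peak_force = numeric(),
                  diastolic_force = numeric(), amplitude = numeric()))
  }
  if (!"force" %in% names(trace)) trace <- trace_to_force(trace)
  tt <- trace$time
  ff <- trace$force
  # traces are sorted in time; windows are located with findInterval
  idx_range <- function(a, b) {
    i0 <- findInterval(a, tt, left.open = TRUE) + 1L
    i1 <- findInterval(b, tt)
    if (i0 > i1) integer() else i0:i1
  }
  reg <- schedule$time[schedule$tag == "regular"]
  events <- purrr::map(seq_along(reg), function(i) {
    t0 <- reg[i]
    t1 <- if (i < length(reg)) min(reg[i + 1], t0 + max_window) else
      min(max(tt), t0 + max_window)
    base_idx <- idx_range(t0 - baseline_window - 1e-12, t0 - 1e-12)
    win_idx <- idx_range(t0 - 1e-12, t1)
    if (length(base_idx) == 0 || length(win_idx) == 0) return(NULL)
    baseline <- median(ff[base_idx])
    pk <- which.max(ff[win_idx])
    amp <- ff[win_idx][pk] - baseline
    if (amp < min_amplitude) return(NULL)
    above <- which(ff[win_idx] > baseline + 0.1 * amp)
    onset <- if (length(above)) tt[win_idx][above[1]] else tt[win_idx][pk]
    tibble(stimulus_time = t0, onset = onset,
           peak_time = tt[win_idx][pk], peak_force = ff[win_idx][pk],
           diastolic_force = baseline, amplitude = amp)
  })
  dplyr::bind_rows(events)
}

#' Classify one paired-pulse beat
#'
#' Decides whether the extra stimulus of a regular/extra pair elicited a
#' second distinct contraction. A second contraction is scored when, after
#' the extra stimulus, the force rises by at least `theta` times the
#' reference twitch amplitude above the local minimum between the regular
#' peak and the candidate second peak (premature beats are attenuated, so
#' `theta` is deliberately far below 1).
#'
#' @param trace A force-calibrated trace tibble (see [detect_twitches()]).
#' @param regular_time,extra_time Stimulus times of the pair, s.
#' @param reference_amplitude Amplitude of an unconditioned regular twitch,
#'   mN.
#' @param theta Distinct-contraction threshold as a fraction of
#'   `reference_amplitude`.
#' @param window Search window after the extra stimulus, s.
#' @return `"two_contractions"` or `"one_contraction"`.
#' @export
classify_pair <- function(trace, regular_time, extra_time,
                          reference_amplitude, theta = 0.10, window = 1.5) {
  if (extra_time <= regular_time) {
    abort_domain("`extra_time` must be after `regular_time`")
  }
  if (!"force" %in% names(trace)) trace <- trace_to_force(trace)
  tt <- trace$time
  ff <- trace$force
  idx_range <- function(a, b) {
    i0 <- findInterval(a, tt, left.open = TRUE) + 1L
    i1 <- findInterval(b, tt)
    if (i0 > i1) integer() else i0:i1
  }
  # After a failed extra stimulus the force decays monotonically towards
  # the diastolic baseline, so the largest forward rise (drawup) after the
  # extra stimulus is noise-sized. A propagated second beat - even one
  # attenuated by restitution and riding on the decay of the regular
  # twitch - produces a drawup of a sizeable fraction of the reference
  # amplitude.
  win <- idx_range(extra_time, extra_time + window)
  if (length(win) < 3) return("one_contraction")
  f <- ff[win]
  drawup <- max(f - cummin(f))
  if (drawup >= theta * reference_amplitude) {
    "two_contractions"
  } else {
    "one_contraction"
  }
}

#' Refractory period from a paired-pulse trace
#'
#' Evaluates every regular/extra pair of a paired-pulse schedule with
#' [classify_pair()], takes a majority vote per interval step (about six
#' pairs per 30 s step at 0.2 Hz), and reports the refractory period as the
#' longest interval whose majority failed to produce two distinct
#' contractions. If every interval produced two contractions the refractory
#' period lies below the protocol floor (`censored = "low"`); if none did,
#' it lies at or above the protocol start (`censored = "high"`).
#'
#' @param trace The trace recorded under `schedule`.
#' @param schedule The paired-pulse schedule used ([paired_pulse_schedule()]).
#' @param precision Reported precision, ms; defaults to the interval
#'   decrement found in the schedule.
#' @param theta Passed to [classify_pair()].
#' @return An object of class `rp_result`: fields `refractory_period` (ms),
#'   `censored` (`"none"`, `"low"`, `"high"`), `precision` (ms) and `steps`,
#'   a tibble with one row per interval (`interval_ms`, `n_pairs`,
#'   `n_two`, `classification`).
#' @export
refractory_period <- function(trace, schedule, precision = NULL,
                              theta = 0.10) {
  if (!inherits(schedule, "stimulus_schedule") ||
      !any(schedule$tag == "extra")) {
    abort_format("`schedule` is not a paired-pulse schedule")
  }
  if (!"force" %in% names(trace)) trace <- trace_to_force(trace)
  if (max(schedule$time) > max(trace$time) + 1e-9) {
    abort_format("schedule extends beyond the trace: protocol/trace mismatch")
  }
  extras <- which(schedule$tag == "extra")
  regs <- extras - 1L
  if (any(schedule$tag[regs] != "regular")) {
    abort_format("malformed schedule: extras must directly follow regulars")
  }
  # reference amplitude: median regular twitch amplitude over the whole run
  ev <- detect_twitches(trace, schedule)
  if (nrow(ev) == 0) {
    abort_format("no twitches found in trace: protocol/trace mismatch")
  }
  ref_amp <- median(ev$amplitude)

  pairs <- tibble(
    regular_time = schedule$time[regs],
    extra_time = schedule$time[extras],
    interval_ms = schedule$interval_ms[extras]
  )
  pairs$class <- purrr::map2_chr(pairs$regular_time, pairs$extra_time,
                                 ~ classify_pair(trace, .x, .y, ref_amp,
                                                 theta = theta))
  steps <- pairs |>
    dplyr::group_by(.data$interval_ms) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_two = sum(.data$class == "two_contractions"),
                     .groups = "drop") |>
    dplyr::mutate(classification = ifelse(.data$n_two > .data$n_pairs / 2,
                                          "two_contractions",
                                          "one_contraction")) |>
    dplyr::arrange(dplyr::desc(.data$interval_ms))

  if (is.null(precision)) {
    dec <- unique(round(-diff(steps$interval_ms), 9))
    precision <- if (length(dec) >= 1) min(dec) else NA_real_
  }

  failing <- steps$interval_ms[steps$classification == "one_contraction"]
  if (length(failing) == 0) {
    rp <- NA_real_; censored <- "low"
  } else if (length(failing) == nrow(steps)) {
    rp <- max(steps$interval_ms); censored <- "high"
  } else {
    rp <- max(failing); censored <- "none"
  }
  structure(
    list(refractory_period = rp, censored = censored, precision = precision,
         steps = steps, reference_amplitude = ref_amp),
    class = "rp_result"
  )
}

#' @export
print.rp_result <- function(x, ...) {
  if (x$censored == "none") {
    cat(sprintf("<rp_result> refractory period %g ms (precision %g ms)\n",
                x$refractory_period, x$precision))
  } else {
    cat(sprintf("<rp_result> censored (%s): RP %s the scanned interval range\n",
                x$censored, if (x$censored == "low") "below" else "at/above"))
  }
  invisible(x)
}

#' Run the full paired-pulse protocol on the digital slice
#'
#' End-to-end refractory-period measurement: simulates the coarse
#' paired-pulse run on the twin, analyses it with [refractory_period()],
#' and, if the protocol requests refinement and the coarse estimate is not
#' censored, simulates a second fine pass over the one-decrement window
#' above the coarse estimate at `fine_step` resolution.
#'
#' @param tissue A [tissue_params()] (its `refractory_period` is the ground
#'   truth being recovered).
#' @param protocol A [paired_pulse_protocol()].
#' @param base_rate Regular pacing rate, Hz.
#' @param pulse Stimulation pulse.
#' @param transducer Transducer calibration.
#' @param seed Sensor-noise seed.
#' @param noise Logical; add sensor noise.
#' @return An `rp_result`; after refinement `precision` equals
#'   `protocol$fine_step` and a `coarse` field holds the first-pass result.
#' @export
#' @examples
#' \donttest{
#' res <- measure_refractory_period(tissue_params(refractory_period = 425),
#'                                  seed = 1)
#' res$refractory_period # 425
#' }
measure_refractory_period <- function(tissue,
                                      protocol = paired_pulse_protocol(),
                                      base_rate = 0.2, pulse = make_pulse(),
                                      transducer = spring_transducer(),
                                      seed = 1, noise = TRUE) {
  run_pass <- function(intervals) {
    sched <- paired_pulse_schedule(protocol, base_rate, pulse,
                                   intervals = intervals)
    dur <- length(intervals) * protocol$step_duration
    tr <- simulate_run(tissue, sched,
                       run_config(duration = dur, seed = seed, noise = noise),
                       transducer)
    refractory_period(tr, sched)
  }
  coarse <- run_pass(protocol_intervals(protocol$start_interval,
                                        protocol$end_interval,
                                        protocol$decrement))
  if (!protocol$fine_refine || coarse$censored != "none") return(coarse)
  hi <- min(coarse$refractory_period + protocol$decrement,
            protocol$start_interval)
  fine_iv <- seq(hi, coarse$refractory_period, by = -protocol$fine_step)
  fine <- run_pass(fine_iv)
  # the fine window may sit entirely above the true RP (coarse grid floor
  # effect); a fully-succeeding fine pass means the coarse estimate stands
  if (fine$censored == "low") {
    out <- coarse
    out$precision <- protocol$fine_step
  } else {
    out <- fine
    out$precision <- protocol$fine_step
  }
  out$coarse <- coarse
  out
}

#' Contracture over a time window
#'
#' Tonic contracture is the spontaneous rise of diastolic tension, scored
#' as the change of the diastolic baseline over a 20-min window. The
#' baseline is estimated per time bin as a low quantile of the force
#' (robust against superimposed twitches), a linear trend is fitted to the
#' bin baselines, and the difference of the fitted trend between window end
#' and start is reported. Negative drift is reported as is.
#'
#' @param trace A force-calibrated trace tibble.
#' @param window Analysis window, min.
#' @param bin Baseline bin width, s.
#' @param prob Baseline quantile within each bin.
#' @return Contracture, mN (positive = rising diastolic tension).
#' @export
contracture <- function(trace, window = 20, bin = 10, prob = 0.1) {
  if (!"force" %in% names(trace)) trace <- trace_to_force(trace)
  t0 <- min(trace$time)
  sel <- trace$time <= t0 + window * 60
  tt <- trace$time[sel]
  ff <- trace$force[sel]
  bins <- floor((tt - t0) / bin)
  base <- tapply(ff, bins, quantile, probs = prob, names = FALSE)
  mid <- (as.numeric(names(base)) + 0.5) * bin
  fit <- lm(as.numeric(base) ~ mid)
  unname(coef(fit)[2]) * (max(mid) - min(mid))
}

#' Per-cycle summary of a long-term recording
#'
#' Partitions a twitch-event stream into medium-exchange cycles and reports
#' the amplitude envelope and the diastolic/systolic force ratio per cycle.
#'
#' @param events A twitch-event tibble ([detect_twitches()] output or
#'   [simulate_longterm_events()]).
#' @param exchange_interval_h Medium-exchange interval, h.
#' @return A tibble with one row per cycle: `cycle`, `t_start_h`,
#'   `min_amplitude`, `max_amplitude`, `diastolic_drift` (mN across the
#'   cycle) and `dia_sys_ratio_pct` (mean diastolic / mean systolic, %).
#' @export
longterm_summary <- function(events, exchange_interval_h = 42) {
  check_positive(exchange_interval_h, "exchange_interval_h")
  events |>
    dplyr::mutate(cycle = floor(.data$stimulus_time /
                                  (exchange_interval_h * 3600))) |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(
      t_start_h = min(.data$stimulus_time) / 3600,
      min_amplitude = min(.data$amplitude),
      max_amplitude = max(.data$amplitude),
      diastolic_drift = dplyr::last(.data$diastolic_force) -
        dplyr::first(.data$diastolic_force),
      dia_sys_ratio_pct = 100 * mean(.data$diastolic_force) /
        mean(.data$peak_force),
      .groups = "drop"
    )
}
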