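#' Charge-balanced biphasic pulse
#'
#' Constant-current stimulation pulse: a charging phase of `amplitude` mA
#' for `charge_width` ms, a zero-current gap, and a discharging phase of
#' opposite polarity. With equal widths the net electrode charge is exactly
#' zero, which is what allows graphite electrodes to run for months without
#' electrochemical damage. The current source is limited to 75 mA and 3 ms
#' per phase.
#'
#' @param amplitude Pulse current, mA, in (0, 75].
#' @param charge_width,gap,discharge_width Phase widths, ms (each phase at
#'   most 3 ms).
#' @return An object of class `pulse_shape` with the phase fields plus
#'   `phase_charge` (uC per phase) and `net_charge` (uC).
#' @export
#' @examples
#' p <- make_pulse() # 50 mA, 1/1/1 ms
#' p$phase_charge    # 50 uC
#' p$net_charge      # 0
make_pulse <- function(amplitude = 50, charge_width = 1, gap = 1,
                       discharge_width = charge_width) {
  check_positive(amplitude, "amplitude")
  if (amplitude > 75) {
    abort_limit("pulse amplitude above the 75 mA current-source ceiling")
  }
  if (charge_width > 3 || discharge_width > 3) {
    abort_limit("phase width above the 3 ms ceiling")
  }
  check_positive(charge_width, "charge_width")
  check_nonnegative(gap, "gap")
  check_positive(discharge_width, "discharge_width")
  structure(
    list(amplitude = amplitude, charge_width = charge_width, gap = gap,
         discharge_width = discharge_width,
         phase_charge = amplitude * charge_width,
         net_charge = amplitude * charge_width - amplitude * discharge_width),
    class = "pulse_shape"
  )
}

#' @export
print.pulse_shape <- function(x, ...) {
  cat(sprintf("<pulse_shape> %g mA, %g/%g/%g ms (net charge %g uC)\n",
              x$amplitude, x$charge_width, x$gap, x$discharge_width,
              x$net_charge))
  invisible(x)
}

#' Sampled current waveform of a pulse
#'
#' @param pulse A [make_pulse()].
#' @param dt Sample interval, ms.
#' @return A tibble with `t_ms` and `current_ma`; the sampled waveform
#'   integrates to the pulse's net charge (zero for balanced widths).
#' @export
pulse_waveform <- function(pulse, dt = 0.01) {
  total <- pulse$charge_width + pulse$gap + pulse$discharge_width
  n <- round(total / dt)
  t <- (seq_len(n) - 0.5) * dt # midpoint sampling keeps the integral exact
  cur <- numeric(n)
  cur[t < pulse$charge_width] <- pulse$amplitude
  cur[t >= pulse$charge_width + pulse$gap] <- -pulse$amplitude
  tibble(t_ms = t, current_ma = cur)
}

#' Regular pacing schedule
#'
#' @param rate Pacing rate, Hz (0.2 Hz is the standard culture rate).
#' @param duration Schedule duration, s.
#' @param pulse A [make_pulse()].
#' @param start Time of the first pulse, s.
#' @return A `stimulus_schedule` tibble with columns `time` (s),
#'   `amplitude`, `charge_width`, `gap`, `discharge_width`, `tag`
#'   (`"regular"`), `interval_ms` (NA for regulars) and `step` (NA).
#'   `floor(duration * rate)` events are generated.
#' @export
#' @examples
#' nrow(pacing_schedule(0.2, 60)) # 12 events in one minute
pacing_schedule <- function(rate = 0.2, duration = 60, pulse = make_pulse(),
                            start = 0.5) {
  check_positive(rate, "rate")
  check_positive(duration, "duration")
  n <- floor(duration * rate)
  times <- start + (seq_len(n) - 1) / rate
  new_schedule(tibble(
    time = times,
    amplitude = pulse$amplitude,
    charge_width = pulse$charge_width,
    gap = pulse$gap,
    discharge_width = pulse$discharge_width,
    tag = "regular",
    interval_ms = NA_real_,
    step = NA_integer_
  ))
}

#' Paired-pulse protocol definition
#'
#' The refractory-period protocol: after every regular pacing stimulus a
#' second ("extra") stimulus is added at a trailing interval; the interval
#' is held for `step_duration` seconds, then decremented, descending from
#' `start_interval` to `end_interval`. The default 25 ms decrement gives 31
#' interval steps (about 15.5 min of protocol). An optional fine pass
#' re-scans a one-decrement window around the coarse transition at
#' `fine_step` resolution.
#'
#' @param start_interval,end_interval Extra-stimulus interval range, ms.
#' @param step_duration Duration of each interval step, s.
#' @param decrement Coarse interval decrement, ms.
#' @param fine_refine Run the fine refinement pass.
#' @param fine_step Fine decrement, ms.
#' @return An object of class `paired_pulse_protocol`.
#' @export
paired_pulse_protocol <- function(start_interval = 1000, end_interval = 250,
                                  step_duration = 30, decrement = 25,
                                  fine_refine = TRUE, fine_step = 1) {
  if (!(start_interval > end_interval && end_interval > 0)) {
    abort_domain("need start_interval > end_interval > 0")
  }
  check_positive(decrement, "decrement")
  check_positive(step_duration, "step_duration")
  check_positive(fine_step, "fine_step")
  structure(
    list(start_interval = start_interval, end_interval = end_interval,
         step_duration = step_duration, decrement = decrement,
         fine_refine = fine_refine, fine_step = fine_step),
    class = "paired_pulse_protocol"
  )
}

protocol_intervals <- function(start, end, decrement) {
  iv <- seq(start, end, by = -decrement)
  if (tail(iv, 1) > end) iv <- c(iv, end)
  iv
}

#' Paired-pulse stimulus schedule
#'
#' Expands a [paired_pulse_protocol()] into a concrete schedule at the given
#' base pacing rate: each step holds one extra-stimulus interval for
#' `step_duration` seconds, and every regular event within the step is
#' followed by an extra event at that interval.
#'
#' @param protocol A [paired_pulse_protocol()].
#' @param base_rate Regular pacing rate, Hz.
#' @param pulse A [make_pulse()].
#' @param intervals Optional explicit interval sequence (ms), overriding the
#'   protocol's coarse ladder (used for the fine pass).
#' @return A `stimulus_schedule` tibble; extra events carry
#'   `tag = "extra"`, their `interval_ms`, and the `step` index.
#' @export
#' @examples
#' sched <- paired_pulse_schedule(paired_pulse_protocol())
#' length(unique(sched$interval_ms[sched$tag == "extra"])) # 31 steps
paired_pulse_schedule <- function(protocol = paired_pulse_protocol(),
                                  base_rate = 0.2, pulse = make_pulse(),
                                  intervals = NULL) {
  if (is.null(intervals)) {
    intervals <- protocol_intervals(protocol$start_interval,
                                    protocol$end_interval,
                                    protocol$decrement)
  }
  if (max(intervals) >= 1000 / base_rate) {
    abort_domain("largest paired-pulse interval must be below the base pacing period")
  }
  per_step <- floor(protocol$step_duration * base_rate)
  if (per_step < 1) abort_domain("step_duration too short for base_rate")
  rows <- purrr::imap(intervals, function(iv, step) {
    t0 <- (step - 1) * protocol$step_duration
    reg_times <- t0 + 0.5 + (seq_len(per_step) - 1) / base_rate
    tibble(
      time = as.numeric(rbind(reg_times, reg_times + iv / 1000)),
      tag = rep(c("regular", "extra"), per_step),
      interval_ms = rep(c(NA_real_, iv), per_step),
      step = as.integer(step)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$amplitude <- pulse$amplitude
  out$charge_width <- pulse$charge_width
  out$gap <- pulse$gap
  out$discharge_width <- pulse$discharge_width
  new_schedule(out[, c("time", "amplitude", "charge_width", "gap",
                       "discharge_width", "tag", "interval_ms", "step")])
}

new_schedule <- function(df) {
  if (is.unsorted(df$time, strictly = TRUE)) {
    abort_format("schedule event times must be strictly increasing")
  }
  class(df) <- c("stimulus_schedule", class(df))
  df
}

#' Electric field strength of a stimulation current
#'
#' Linear calibration between pulse current and field strength in the
#' chamber, `E = c * I` with `c = 0.0078` V/mm/mA (the midpoint of the two
#' printed current/field anchor ratios: 20 mA ~ 0.15 V/mm and 50 mA ~
#' 0.4 V/mm).
#'
#' @param amplitude Pulse current, mA.
#' @return Field strength, V/mm.
#' @export
#' @examples
#' electric_field(c(20, 50))
electric_field <- function(amplitude) {
  if (any(amplitude < 0)) abort_domain("`amplitude` must be non-negative")
  0.0078 * amplitude
}
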