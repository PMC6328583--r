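#' Simulation run configuration
#'
#' @param duration Run duration, s.
#' @param sample_rate Acquisition rate per chamber, samples/s (the recorder
#'   polls each chamber at 500 samples/s).
#' @param seed Seed for the sensor-noise stream; mandatory when
#'   `noise = TRUE` so that runs are bit-reproducible.
#' @param noise Add calibrated sensor noise to the flux channel.
#' @param preload Target diastolic preload, mN, established by
#'   [adjust_preload()] before the run.
#' @param chamber_id Chamber identifier (1-8 on one platform).
#' @param rate_bpm Pacing rate used for the force-frequency factor; if
#'   `NULL` it is derived from the regular-event spacing of the schedule.
#' @param modulation Optional slow multiplicative modulation of twitch
#'   amplitude emulating medium-exchange cycles: a list with `period_h` and
#'   `depth`; amplitude drops to `1 - depth` at each exchange and recovers
#'   linearly over the cycle. Off (`NULL`) by default.
#' @return An object of class `run_config`.
#' @export
run_config <- function(duration = 60, sample_rate = 500, seed = NULL,
                       noise = TRUE, preload = 1, chamber_id = 1,
                       rate_bpm = NULL, modulation = NULL) {
  check_positive(duration, "duration")
  check_positive(sample_rate, "sample_rate")
  if (noise && is.null(seed)) {
    abort_domain("a `seed` is mandatory for runs with sensor noise")
  }
  structure(
    list(duration = duration, sample_rate = sample_rate, seed = seed,
         noise = noise, preload = preload, chamber_id = chamber_id,
         rate_bpm = rate_bpm, modulation = modulation),
    class = "run_config"
  )
}

modulation_factor <- function(t_s, modulation) {
  if (is.null(modulation)) return(rep(1, length(t_s)))
  period_s <- modulation$period_h * 3600
  frac <- (t_s %% period_s) / period_s
  (1 - modulation$depth) + modulation$depth * frac
}

#' Simulate a raw sensor trace
#'
#' Runs the digital slice through a stimulus schedule and emits the raw
#' acquisition stream: per sample the magnetic flux at the sensor plus the
#' stimulation-current marker. The chamber is first brought to the
#' configured preload; each schedule event is passed through the
#' excitability gate ([excitable()]): events that fall into the refractory
#' period or are sub-threshold do not trigger a twitch. Tissue force
#' (preload plus the superposition of active twitches, scaled by
#' length-tension, force-frequency and premature-beat restitution) is
#' converted to spring-tip displacement and flux, and Gaussian sensor noise
#' with the calibrated per-sample amplitude is added.
#'
#' @param tissue A [tissue_params()].
#' @param schedule A stimulus schedule ([pacing_schedule()],
#'   [paired_pulse_schedule()], or an empty/NULL schedule for an
#'   unstimulated trace).
#' @param config A [run_config()].
#' @param transducer A [spring_transducer()].
#' @return A `myo_trace` tibble with columns `time` (s), `flux` (T),
#'   `stim_current` (mA, marker at the stimulus sample) and `tag`. The
#'   transducer calibration, sample rate, chamber id and geometry travel as
#'   attributes and are serialised by [write_trace()].
#' @export
#' @examples
#' tr <- simulate_run(tissue_params(), pacing_schedule(0.2, 30),
#'                    run_config(duration = 30, seed = 1))
simulate_run <- function(tissue, schedule = NULL,
                         config = run_config(),
                         transducer = spring_transducer()) {
  stopifnot(inherits(tissue, "tissue_params"))
  fs <- config$sample_rate
  n <- floor(config$duration * fs)
  t <- (seq_len(n) - 1) / fs

  if (!is.null(schedule) && nrow(schedule) > 0 &&
      max(schedule$time) > config$duration) {
    abort_format("schedule events extend beyond the run duration")
  }

  state <- adjust_preload(chamber_state(), tissue, target = config$preload)
  lambda <- operating_fraction(state, tissue)
  diastolic <- state$preload

  rate_bpm <- config$rate_bpm
  if (is.null(rate_bpm)) {
    reg <- if (is.null(schedule)) numeric() else
      schedule$time[schedule$tag == "regular"]
    rate_bpm <- if (length(reg) >= 2) 60 / median(diff(reg)) else 12
  }

  base_amp <- tissue$peak_twitch_force *
    active_length_factor(tissue, lambda) *
    ffr_factor(rate_bpm, tissue$ffr)

  force <- rep(diastolic, n)
  activations <- list()
  if (!is.null(schedule) && nrow(schedule) > 0) {
    for (i in seq_len(nrow(schedule))) {
      ex <- excitable(tissue, state, schedule$time[i],
                      schedule$amplitude[i], schedule$charge_width[i])
      state <- ex$state
      if (ex$activated) {
        activations[[length(activations) + 1L]] <-
          c(time = schedule$time[i],
            amp = base_amp * restitution_factor(ex$interval_ms, tissue) *
              modulation_factor(schedule$time[i], config$modulation))
      }
    }
  }

  horizon <- (tissue$time_to_peak + 8 * tissue$relaxation_tau) / 1000
  for (a in activations) {
    i0 <- max(1L, ceiling(a[["time"]] * fs) + 1L)
    i1 <- min(n, floor((a[["time"]] + horizon) * fs) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    dt_ms <- (t[idx] - a[["time"]]) * 1000
    force[idx] <- force[idx] + a[["amp"]] * twitch_shape(dt_ms, tissue)
  }

  x_mm <- force / transducer$spring_constant
  flux <- transducer$baseline_flux + transducer$sensitivity * x_mm * 1e-3
  if (any(abs(flux - transducer$baseline_flux) > 1.2e-3)) {
    warn("flux excursion beyond the 1.2 mT operating budget",
         class = "myoslice_saturation_warning")
  }
  if (config$noise) {
    flux <- flux + with_seed(config$seed, rnorm(n, 0, transducer$noise_sd))
  }

  stim_current <- numeric(n)
  tag <- character(n)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    marker <- pmin(n, floor(schedule$time * fs) + 1L)
    stim_current[marker] <- schedule$amplitude
    tag[marker] <- schedule$tag
  }

  out <- tibble(time = t, flux = flux, stim_current = stim_current, tag = tag)
  attr(out, "transducer") <- transducer
  attr(out, "sample_rate") <- fs
  attr(out, "chamber_id") <- config$chamber_id
  attr(out, "geometry") <- tissue$geometry
  class(out) <- c("myo_trace", class(out))
  out
}

#' Synthetic long-term contractility event stream
#'
#' Generates weeks of per-beat twitch summaries (not raw 500 Hz samples) for
#' long-term trend analysis: the medium-exchange amplitude modulation and
#' the slow decline of the diastolic/systolic force ratio from 23% at the
#' start of culture to 14% after four weeks.
#'
#' @param days Stream duration, days.
#' @param exchange_interval_h Medium-exchange interval, h.
#' @param depth Amplitude modulation depth over one exchange cycle.
#' @param diastolic Diastolic force, mN.
#' @param ratio_start,ratio_end Diastolic/systolic force ratio at day 0 and
#'   at `ratio_days` of culture.
#' @param ratio_days Days over which the ratio declines.
#' @param cadence_s Event spacing, s.
#' @return A tibble shaped like [detect_twitches()] output:
#'   `stimulus_time` (s), `peak_force`, `diastolic_force`, `amplitude`.
#' @export
simulate_longterm_events <- function(days = 28, exchange_interval_h = 42,
                                     depth = 0.3, diastolic = 1,
                                     ratio_start = 0.23, ratio_end = 0.14,
                                     ratio_days = 28, cadence_s = 60) {
  t_s <- seq(0, days * 86400, by = cadence_s)
  ratio <- ratio_start +
    (ratio_end - ratio_start) * pmin(t_s / (ratio_days * 86400), 1)
  amp_full <- diastolic / ratio - diastolic
  mod <- modulation_factor(t_s, list(period_h = exchange_interval_h,
                                     depth = depth))
  amp <- amp_full * mod
  tibble(stimulus_time = t_s,
         peak_force = diastolic + amp,
         diastolic_force = diastolic,
         amplitude = amp)
}
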