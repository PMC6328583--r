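# shared fixtures: everything is generated in code at test time

default_tissue <- function(...) tissue_params(...)

# short noise-free paced trace plus its schedule
paced_fixture <- function(duration = 60, rate = 0.2, seed = 1,
                          noise = FALSE, tissue = tissue_params()) {
  sched <- pacing_schedule(rate, duration)
  trace <- simulate_run(tissue, sched,
                        run_config(duration = duration, seed = seed,
                                   noise = noise))
  list(trace = trace, schedule = sched, tissue = tissue)
}

expect_no_saturation <- function(expr) {
  expect_silent(suppressMessages(expr))
}
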