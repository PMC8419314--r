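prot <- build_seventeen_pulse_protocol(protocol_config())

flat_trace <- function(dt = 0.05, period = 1000) {
  t <- seq(0, period - dt, by = dt)
  data.frame(time_ms = t, current_nA = numeric(length(t)))
}

test_that("an all-zero trace yields 17 zero peaks", {
  pk <- extract_peaks(flat_trace(), prot)
  expect_equal(unname(pk), rep(0, 17))
})

test_that("a known deflection on a leak ramp is recovered exactly", {
  tr <- flat_trace()
  tr$current_nA <- 0.4 + 0.002 * tr$time_ms      # constant + linear leak
  pw <- pulse_windows(prot)
  in1 <- tr$time_ms >= pw$start_ms[1] + 1 & tr$time_ms <= pw$start_ms[1] + 3
  tr$current_nA[in1] <- tr$current_nA[in1] - 3   # -3 nA square deflection
  pk <- extract_peaks(tr, prot, blank_ms = 0.2, leak_mode = "baseline_linear")
  expect_equal(unname(pk[1]), -3, tolerance = 1e-6)
  expect_equal(unname(pk[-1]), rep(0, 16), tolerance = 1e-6)
})

test_that("peak extraction is invariant to linear-in-time leak", {
  channel <- channel_model()
  drug <- mechanism_preset("riluzole_like")
  sw <- simulate_sweep(channel, drug, prot, 30, return_trace = TRUE)
  clean <- extract_peaks(sw$trace, prot)
  leaky <- sw$trace
  leaky$current_nA <- leaky$current_nA - 0.8 + 0.0015 * leaky$time_ms
  pk <- extract_peaks(leaky, prot)
  expect_equal(pk, clean, tolerance = 1e-6)
})

test_that("trace peaks reproduce the simulator's reported peaks", {
  channel <- channel_model()
  drug <- mechanism_preset("riluzole_like")
  for (cc in c(0, 100)) {
    sw <- simulate_sweep(channel, drug, prot, cc, return_trace = TRUE)
    pk <- extract_peaks(sw$trace, prot, blank_ms = 0.2)
    expect_equal(pk, sw$peaks, tolerance = 0.01)
  }
})

test_that("invalid extraction windows are rejected", {
  expect_error(extract_peaks(flat_trace(), prot, blank_ms = 5),
               "blanking window")
  short <- flat_trace(period = 500)   # misses the SSI pulses
  expect_error(extract_peaks(short, prot), "no samples")
})

test_that("phase annotation tags the documented analysis windows", {
  amps <- expand.grid(sweep_index = 1:80, pulse_index = 1:17)
  amps$time_s <- amps$sweep_index - 1
  amps$amplitude_nA <- -5
  sched <- perfusion_schedule(c(20, 60), c(0, 100))
  ann <- annotate_phases(amps, sched, control_window_s = 5, drug_window_s = 5)
  expect_equal(sum(ann$phase == "control_1") / 17, 5)
  expect_equal(sum(ann$phase == "drug_1") / 17, 5)
  expect_setequal(unique(ann$sweep_index[ann$phase == "control_1"]), 16:20)
  expect_setequal(unique(ann$sweep_index[ann$phase == "drug_1"]), 76:80)
})

test_that("each application is normalized to its own control window", {
  amps <- expand.grid(sweep_index = 1:60, pulse_index = 1:17)
  amps$time_s <- amps$sweep_index - 1
  amps$amplitude_nA <- -5
  sched <- perfusion_schedule(c(15, 15, 15, 15), c(0, 10, 0, 30))
  ann <- annotate_phases(amps, sched)
  expect_setequal(unique(ann$sweep_index[ann$phase == "control_1"]), 11:15)
  expect_setequal(unique(ann$sweep_index[ann$phase == "control_2"]), 41:45)
  apps <- attr(ann, "applications")
  expect_equal(apps$conc_uM, c(10, 30))
})

test_that("degenerate schedules are rejected", {
  amps <- expand.grid(sweep_index = 1:10, pulse_index = 1:17)
  amps$time_s <- amps$sweep_index - 1
  amps$amplitude_nA <- -5
  expect_error(annotate_phases(amps, data.frame()[0, ]), "empty")
  expect_error(annotate_phases(amps, perfusion_schedule(c(5, 10), c(0, 10))),
               "covers")
  expect_error(annotate_phases(amps, perfusion_schedule(c(5, 5), c(0, 0))),
               "no drug application")
})

test_that("amplitude tables round-trip through disk", {
  amps <- expand.grid(sweep_index = 1:12, pulse_index = 1:17)
  amps$time_s <- amps$sweep_index - 1
  amps$amplitude_nA <- rnorm(nrow(amps), -5, 0.1)
  amps$conc_uM <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write_amplitudes(amps, path)
  back <- read_amplitudes(path)
  expect_equal(back$amplitude_nA, amps$amplitude_nA, tolerance = 1e-12)
  expect_equal(back$pulse_index, amps$pulse_index)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_amplitudes(amps[amps$pulse_index != 9, ], p2)
  expect_error(read_amplitudes(p2), "pulse indices 1..17")
})

test_that("peaks_from_traces rebuilds the amplitude table from raw sweeps", {
  channel <- channel_model()
  drug <- mechanism_preset("ttx_like")
  sched <- perfusion_schedule(c(2, 2), c(0, 0.03))
  ex <- simulate_experiment(channel, drug, prot, sched, noise_sd = 0,
                            seed = 6, keep_traces = TRUE)
  remeasured <- peaks_from_traces(ex)
  expect_identical(nrow(remeasured), nrow(ex$amplitudes))
  merged <- merge(remeasured, ex$amplitudes,
                  by = c("sweep_index", "pulse_index"))
  expect_equal(merged$amplitude_nA.x, merged$amplitude_nA.y,
               tolerance = 0.01)
})
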