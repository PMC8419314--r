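channel <- channel_model()
prot <- build_seventeen_pulse_protocol(protocol_config())

test_that("drug-free sweeps are invariant to drug parameters", {
  d1 <- compound_mechanism(k_on = 0.01, K_R = 300, K_I = 3)
  d2 <- compound_mechanism(k_on = 5, K_R = 2, K_I = 2,
                           access_factors = c(C1 = 0.1))
  s1 <- simulate_sweep(channel, d1, prot, 0)
  s2 <- simulate_sweep(channel, d2, prot, 0)
  # identical up to eigensolver roundoff (the generators share no binding
  # flux at zero concentration but differ in their bound blocks)
  expect_equal(s1$peaks, s2$peaks, tolerance = 1e-10)
  expect_true(all(s1$peaks < 0))  # inward currents
})

test_that("state-independent blocker at conc = K halves every pulse", {
  K <- 10
  blocker <- compound_mechanism(k_on = 1, K_R = K, K_I = K)  # fast binding
  ctrl <- simulate_sweep(channel, blocker, prot, 0)
  # settle into the periodic regime at the test concentration
  sw <- simulate_sweep(channel, blocker, prot, K)
  sw <- simulate_sweep(channel, blocker, prot, K, init = sw$final_occupancy)
  inh <- 1 - sw$peaks / ctrl$peaks
  expect_true(all(abs(inh - 0.5) < 0.02))
})

test_that("equilibrium-limit inhibition matches the binding isotherm", {
  K <- 10
  blocker <- compound_mechanism(k_on = 1, K_R = K, K_I = K)
  ctrl <- simulate_sweep(channel, blocker, prot, 0)
  for (cc in c(3, 30)) {
    sw <- simulate_sweep(channel, blocker, prot, cc)
    sw <- simulate_sweep(channel, blocker, prot, cc,
                         init = sw$final_occupancy)
    inh <- 1 - sw$peaks / ctrl$peaks
    expect_true(all(abs(inh - cc / (cc + K)) < 0.03))
  }
})

test_that("state-dependent compounds inhibit depolarized pulses more", {
  drug <- mechanism_preset("riluzole_like")
  ctrl <- simulate_sweep(channel, drug, prot, 0)
  sw <- simulate_sweep(channel, drug, prot, 100)
  sw <- simulate_sweep(channel, drug, prot, 100, init = sw$final_occupancy)
  inh <- 1 - sw$peaks / ctrl$peaks
  expect_gt(inh["17"], inh["1"])
  expect_gt(inh["7"], inh["1"])    # short gap keeps channels inhibited
  expect_lt(inh["1"], 0.15)        # rested pulse barely touched
})

test_that("inhibition is monotone in concentration at every pulse", {
  drug <- mechanism_preset("lidocaine_like")
  ctrl <- simulate_sweep(channel, drug, prot, 0)
  prev <- rep(-Inf, 17)
  for (cc in c(0, 30, 100, 300, 1000)) {
    sw <- simulate_sweep(channel, drug, prot, cc)
    sw <- simulate_sweep(channel, drug, prot, cc, init = sw$final_occupancy)
    inh <- 1 - sw$peaks / ctrl$peaks
    expect_true(all(inh >= prev - 1e-6))
    prev <- inh
  }
})

test_that("occupancy stays conserved across whole sweeps", {
  drug <- mechanism_preset("riluzole_like")
  sw <- simulate_sweep(channel, drug, prot, 100)
  expect_equal(sum(sw$final_occupancy), 1, tolerance = 1e-9)
  expect_true(all(sw$final_occupancy >= 0))
})

test_that("experiments are bitwise reproducible under a fixed seed", {
  drug <- mechanism_preset("ttx_like")
  sched <- perfusion_schedule(c(8, 8), c(0, 0.03))
  e1 <- simulate_experiment(channel, drug, prot, sched, seed = 42)
  e2 <- simulate_experiment(channel, drug, prot, sched, seed = 42)
  expect_identical(e1$amplitudes, e2$amplitudes)
  e3 <- simulate_experiment(channel, drug, prot, sched, seed = 43)
  expect_false(identical(e1$amplitudes, e3$amplitudes))
  expect_error(simulate_experiment(channel, drug, prot, sched),
               "seed is mandatory")
  expect_error(
    simulate_experiment(channel, drug, prot,
                        data.frame(block = 1, n_sweeps = 5, conc_uM = -1),
                        seed = 1),
    "negative target concentration")
})

test_that("washout returns the rested pulse to its control level", {
  blocker <- compound_mechanism(k_on = 1, K_R = 10, K_I = 10,
                                perfusion_tau_s = 1.5)
  sched <- perfusion_schedule(c(15, 15, 20), c(0, 10, 0))
  ex <- simulate_experiment(channel, blocker, prot, sched,
                            noise_sd = 0.02, seed = 3)
  a <- ex$amplitudes
  ctrl <- abs(a$amplitude_nA[a$block == 1 & a$pulse_index == 1])
  late <- abs(a$amplitude_nA[a$block == 3 & a$pulse_index == 1 &
                               a$sweep_index > 45])
  # ten perfusion time constants after washout start: residual drug is gone
  expect_lt(abs(mean(late) - mean(ctrl)) / mean(ctrl),
            3 * 0.02 * sqrt(1 / 5 + 1 / 15))
})

test_that("washout kinetics recover the perfusion time constant", {
  # sub-saturating concentration: amplitude tracks concentration linearly,
  # so the amplitude washout is a clean single exponential with tau
  blocker <- compound_mechanism(k_on = 1, K_R = 10, K_I = 10,
                                perfusion_tau_s = 3.5)
  sched <- perfusion_schedule(c(10, 20, 35), c(0, 2, 0))
  ex <- simulate_experiment(channel, blocker, prot, sched,
                            noise_sd = 0.005, seed = 8)
  fit <- macro_offset_tau(ex$amplitudes, pulse_index = 17, washout_block = 3)
  expect_identical(fit$flag, "ok")
  expect_equal(fit$tau_s, 3.5, tolerance = 0.5 / 3.5)
})

test_that("ground-truth sidecar serializes the mechanism", {
  drug <- mechanism_preset("riluzole_like")
  sched <- perfusion_schedule(c(3, 3), c(0, 30))
  ex <- simulate_experiment(channel, drug, prot, sched, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(ex, path)
  gt <- jsonlite::read_json(path)
  expect_equal(gt$K_R_uM, drug$K_R)
  expect_equal(gt$K_I_uM, drug$K_I)
  expect_equal(gt$seed, 1L)
})
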