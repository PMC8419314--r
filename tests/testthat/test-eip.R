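prot <- build_seventeen_pulse_protocol(protocol_config())

synthetic_series <- function(drug_scale, n_ctrl = 10, n_drug = 10,
                             conc = 100) {
  # one application; control peaks -5 nA, drug peaks scaled per pulse
  n <- n_ctrl + n_drug
  amps <- expand.grid(sweep_index = seq_len(n), pulse_index = 1:17)
  amps$time_s <- amps$sweep_index - 1
  amps$amplitude_nA <- -5
  drugged <- amps$sweep_index > n_ctrl
  amps$amplitude_nA[drugged] <-
    -5 * drug_scale[amps$pulse_index[drugged]]
  sched <- perfusion_schedule(c(n_ctrl, n_drug), c(0, conc))
  annotate_phases(amps, sched)
}

test_that("identical drug and control phases give unit ratios", {
  ann <- synthetic_series(rep(1, 17))
  rt <- make_ratio_table(ann)
  expect_equal(rt$ratio, rep(1, 17))
  expect_equal(unique(rt$conc_uM), 100)
})

test_that("complete block gives zero ratios", {
  ann <- synthetic_series(rep(0, 17))
  rt <- make_ratio_table(ann)
  expect_equal(rt$ratio, rep(0, 17))
})

test_that("a zero control mean is reported with the offending pulse", {
  ann <- synthetic_series(rep(1, 17))
  ann$amplitude_nA[ann$pulse_index == 9 & grepl("control", ann$phase)] <- 0
  expect_error(make_ratio_table(ann), "pulse #9")
})

test_that("a fast-offset state-dependent compound spares rested pulses", {
  sim <- sim_experiment("riluzole_like", seed = 21)
  res <- run_analyze(sim$experiment, config = sim$cfg)
  rt <- res$ratio_table
  mid <- rt[rt$conc_uM == 100, ]
  expect_gt(mid$ratio[mid$pulse_index == 1], 0.8)
  expect_lt(mid$ratio[mid$pulse_index == 17], 0.5)
  expect_lt(mid$ratio[mid$pulse_index == 7], 0.5)

  # potency fades monotonically as the recovery gap lengthens
  rfi <- eip_section(res$eip_curves, "RFI")
  expect_true(all(diff(rfi$ic50_uM) > 0))
})

test_that("EIP fitting requires at least three concentrations", {
  ann <- synthetic_series(rep(0.5, 17))
  rt <- make_ratio_table(ann)
  expect_error(build_eip_curves(rt, prot), "at least 3 concentrations")
})

test_that("a state-independent fast blocker yields a flat EIP profile", {
  K <- 10
  blocker <- compound_mechanism(k_on = 1, K_R = K, K_I = K,
                                perfusion_tau_s = 1.5, name = "flat")
  sim <- sim_experiment(NULL, mechanism = blocker, concs = c(3, 10, 30),
                        seed = 31)
  res <- run_analyze(sim$experiment, config = sim$cfg)
  ic <- tapply(res$eip_curves$ic50_uM, res$eip_curves$pulse_index, mean)
  expect_true(all(abs(ic - K) / K < 0.15))
})

test_that("slow-onset state-dependent EIP develops along the SDO axis", {
  # onset takes tens of ms, so potency visibly grows with conditioning
  # duration (for fast-onset compounds the SDO section saturates instead)
  sim <- sim_experiment("lidocaine_like", seed = 41)
  res <- run_analyze(sim$experiment, config = sim$cfg)
  sdo <- eip_section(res$eip_curves, "SDO")
  expect_true(all(diff(sdo$ic50_uM) < 0))
  # recovery beyond the availability-limited short gaps raises the IC50
  rfi <- eip_section(res$eip_curves, "RFI")
  late <- rfi$ic50_uM[rfi$x_value >= 8]
  expect_true(all(diff(late) > 0))
  # SSI: potency grows with depolarized holding
  ssi <- eip_section(res$eip_curves, "SSI")
  expect_true(all(diff(ssi$ic50_uM) < 0))
})

test_that("fitted potencies stay between the state affinities", {
  drug <- compound_mechanism(k_on = 1 / 30, K_R = 1000, K_I = 10,
                             perfusion_tau_s = 2, name = "bracketing")
  sim <- sim_experiment(NULL, mechanism = drug,
                        concs = c(10, 30, 100, 300, 1000), seed = 51)
  res <- run_analyze(sim$experiment, config = sim$cfg)
  ic <- res$eip_curves$ic50_uM
  expect_true(all(ic > drug$K_I / 1.5))
  expect_true(all(ic < drug$K_R * 1.5))
})

test_that("pulses shared between sections appear in each of them", {
  ann <- synthetic_series(seq(0.2, 0.9, length.out = 17)[c(17:1)])
  # build three synthetic applications to satisfy the 3-concentration rule
  rt <- do.call(rbind, lapply(c(30, 100, 300), function(cc) {
    r <- make_ratio_table(synthetic_series(
      1 - (1 - seq(0.2, 0.9, length.out = 17)) * cc / 300, conc = cc))
    r
  }))
  curves <- build_eip_curves(rt, prot)
  expect_identical(sum(curves$pulse_index == 12), 2L)   # RFI and SSI
  expect_identical(sum(curves$pulse_index == 1), 1L)    # RFI only
  path <- withr::local_tempfile(fileext = ".csv")
  write_eip_table(curves, path)
  expect_true(file.exists(path))
})
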