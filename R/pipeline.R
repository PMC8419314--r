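# End-to-end pipeline orchestration --------------------------------------

#' Assemble a run configuration
#'
#' Bundles everything a simulation + analysis run needs: the protocol
#' configuration, the simulated compound mechanism, the perfusion schedule
#' and the analysis options. The seed is mandatory; every stochastic step
#' derives from it.
#'
#' @param mechanism a [compound_mechanism()] or a preset name for
#'   [mechanism_preset()].
#' @param concentrations_uM applied concentrations, one application each.
#' @param protocol a [protocol_config()].
#' @param sweeps_per_block sweeps per schedule block (control and drug
#'   blocks alike).
#' @param noise_sd multiplicative peak noise s.d.
#' @param rundown_per_sweep linear rundown per sweep.
#' @param control_window_s,drug_window_s analysis windows.
#' @param seed integer seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(mechanism = "riluzole_like",
                       concentrations_uM = NULL,
                       protocol = protocol_config(),
                       sweeps_per_block = 30,
                       noise_sd = 0.02,
                       rundown_per_sweep = 0,
                       control_window_s = 5,
                       drug_window_s = 5,
                       seed = 1) {
  if (is.character(mechanism)) {
    if (is.null(concentrations_uM))
      concentrations_uM <- preset_concentrations(mechanism)
    mechanism <- mechanism_preset(mechanism)
  }
  if (is.null(concentrations_uM))
    stop("field 'concentrations_uM' is required when the mechanism is not a preset")
  required_mech <- c("k_on", "K_R", "K_I", "perfusion_tau_s")
  for (f in required_mech)
    if (is.null(mechanism[[f]]))
      stop("mechanism config misses field '", f, "'")
  if (is.null(seed)) stop("field 'seed' is required")
  stopifnot(sweeps_per_block >= 2, noise_sd >= 0)
  cfg <- list(mechanism = mechanism,
              concentrations_uM = concentrations_uM,
              protocol = protocol,
              sweeps_per_block = as.integer(sweeps_per_block),
              noise_sd = noise_sd,
              rundown_per_sweep = rundown_per_sweep,
              control_window_s = control_window_s,
              drug_window_s = drug_window_s,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Interleaved control/drug perfusion schedule of a run
#'
#' One drug-free block before every application, plus a terminal washout
#' block: C D1 C D2 ... C Dk C.
#'
#' @param config a [run_config()].
#' @return a [perfusion_schedule()].
#' @export
config_schedule <- function(config) {
  k <- length(config$concentrations_uM)
  n <- config$sweeps_per_block
  perfusion_schedule(
    n_sweeps = rep(n, 2 * k + 1),
    conc_uM = as.vector(rbind(0, config$concentrations_uM))[seq_len(2 * k)] |>
      c(0)
  )
}

#' Simulate a full experiment from a run configuration
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes the amplitude
#'   table (\code{amplitudes.csv}), the protocol (\code{protocol.yaml}) and
#'   the ground-truth sidecar (\code{ground_truth.json}).
#' @param keep_traces store full current traces.
#' @return a \code{simulated_experiment}.
#' @export
run_simulate <- function(config, out_dir = NULL, keep_traces = FALSE) {
  stopifnot(inherits(config, "run_config"))
  prot <- build_seventeen_pulse_protocol(config$protocol)
  channel <- channel_model()
  exper <- simulate_experiment(channel, config$mechanism, prot,
                               config_schedule(config),
                               noise_sd = config$noise_sd,
                               rundown_per_sweep = config$rundown_per_sweep,
                               seed = config$seed,
                               keep_traces = keep_traces)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    amps <- annotate_phases(exper$amplitudes, exper$schedule,
                            config$control_window_s, config$drug_window_s)
    write_amplitudes(amps, file.path(out_dir, "amplitudes.csv"))
    write_protocol(prot, file.path(out_dir, "protocol.yaml"))
    write_ground_truth(exper, file.path(out_dir, "ground_truth.json"))
  }
  exper
}

#' Analyze an experiment into EIP curves and a compound summary
#'
#' The full analysis chain: phase annotation, drug/control ratio table,
#' per-pulse Hill fits arranged as SDO/RFI/SSI potency curves, the
#' inactivated fraction, affinity estimates and kinetic descriptors
#' (including the macroscopic offset fitted on the terminal washout block
#' when one is present).
#'
#' @param experiment a \code{simulated_experiment}, or an amplitude table
#'   (data frame / path to \code{amplitudes.csv}) together with
#'   \code{protocol} and \code{schedule}.
#' @param protocol,schedule required when \code{experiment} is a bare
#'   amplitude table.
#' @param config analysis options (a [run_config()]; windows and id).
#' @param measurement_id label for the outputs.
#' @return list with \code{amplitudes}, \code{ratio_table},
#'   \code{eip_curves}, \code{h} and \code{summary}.
#' @export
run_analyze <- function(experiment, protocol = NULL, schedule = NULL,
                        config = NULL, measurement_id = "m1") {
  cw <- if (is.null(config)) 5 else config$control_window_s
  dw <- if (is.null(config)) 5 else config$drug_window_s
  if (inherits(experiment, "simulated_experiment")) {
    amps_raw <- experiment$amplitudes
    protocol <- experiment$protocol
    schedule <- experiment$schedule
  } else {
    if (is.character(experiment)) experiment <- read_amplitudes(experiment)
    amps_raw <- experiment
    if (is.null(protocol) || is.null(schedule))
      stop("protocol and schedule are required for bare amplitude tables")
  }
  amps <- annotate_phases(amps_raw, schedule, cw, dw)
  ratios <- make_ratio_table(amps)
  curves <- build_eip_curves(ratios, protocol, measurement_id)
  h <- fraction_inactivated(amps)
  washout <- NULL
  last <- nrow(schedule)
  if (schedule$conc_uM[last] == 0 && last > 1 &&
      schedule$conc_uM[last - 1] > 0 && schedule$n_sweeps[last] >= 10)
    washout <- amps_raw[amps_raw$block == schedule$block[last] &
                          amps_raw$pulse_index == 17,
                        c("time_s", "amplitude_nA")]
  summ <- compound_summary(curves, h, washout, measurement_id)
  list(amplitudes = amps, ratio_table = ratios, eip_curves = curves,
       h = h, summary = summ)
}

#' Generate the bundled mechanism presets as fixture files
#'
#' Writes, for each of the five presets, a mechanism configuration (YAML)
#' and a ground-truth sidecar (JSON); optionally also a small simulated
#' amplitude table per preset.
#'
#' @param dir output directory.
#' @param seed integer seed used for any simulated fixture.
#' @param simulate also run a short simulated experiment per preset.
#' @param sweeps_per_block block length for the simulated fixtures.
#' @return invisibly, the vector of preset names written.
#' @export
make_fixtures <- function(dir, seed = 1, simulate = FALSE,
                          sweeps_per_block = 10) {
  presets <- c("riluzole_like", "lidocaine_like", "benzocaine_like",
               "bupivacaine_like", "ttx_like")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in presets) {
    mech <- mechanism_preset(p)
    mech_out <- unclass(mech)
    if (!is.null(mech_out$access_factors))
      mech_out$access_factors <- as.list(mech_out$access_factors)
    yaml::write_yaml(mech_out, file.path(dir, paste0(p, ".yaml")))
    jsonlite::write_json(
      ground_truth(channel_model(), mech, 0.02, 0, seed),
      file.path(dir, paste0(p, "_truth.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (simulate) {
      cfg <- run_config(mechanism = p, seed = seed,
                        sweeps_per_block = sweeps_per_block,
                        control_window_s = min(5, sweeps_per_block),
                        drug_window_s = min(5, sweeps_per_block))
      run_simulate(cfg, out_dir = file.path(dir, p))
    }
  }
  invisible(presets)
}

#' Read a mechanism configuration file
#'
#' @param path YAML file as written by [make_fixtures()].
#' @return a [compound_mechanism()].
#' @export
read_mechanism <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("k_on", "K_R", "K_I", "perfusion_tau_s")
  for (f in required)
    if (is.null(cfg[[f]])) stop("mechanism config misses field '", f, "'")
  compound_mechanism(k_on = cfg$k_on, K_R = cfg$K_R, K_I = cfg$K_I,
                     access_factors = if (length(cfg$access_factors))
                       unlist(cfg$access_factors) else NULL,
                     perfusion_tau_s = cfg$perfusion_tau_s,
                     inactivated_states = if (is.null(cfg$inactivated_states))
                       "I" else unlist(cfg$inactivated_states),
                     bound_conducting = isTRUE(cfg$bound_conducting),
                     name = if (is.null(cfg$name)) "compound" else cfg$name)
}
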