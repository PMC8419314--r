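# Whole-cell current simulation under step protocols ---------------------

open_unbound_idx <- function(channel) match(channel$open_states, channel$states)

open_bound_idx <- function(channel)
  length(channel$states) + match(channel$open_states, channel$states)

conducting_occupancy <- function(P, channel, drug) {
  iu <- open_unbound_idx(channel)
  occ <- rowSums(P[, iu, drop = FALSE])
  if (isTRUE(drug$bound_conducting))
    occ <- occ + rowSums(P[, open_bound_idx(channel), drop = FALSE])
  occ
}

#' Simulate one sweep of a step protocol
#'
#' Propagates the channel-drug occupancy through every segment of the
#' protocol at a fixed applied concentration, sampling the conducting
#' occupancy on a fine grid inside each test pulse to locate the peak
#' current. Occupancy is chained across segments, and the returned final
#' occupancy lets callers chain consecutive sweeps.
#'
#' @param channel a [channel_model()].
#' @param drug a [compound_mechanism()].
#' @param protocol a \code{voltage_protocol}.
#' @param conc applied concentration during the sweep, uM.
#' @param init initial occupancy over the doubled state space; default is
#'   the drug-free equilibrium at the holding potential.
#' @param peak_dt_ms sampling step inside test pulses for peak detection.
#' @param return_trace if TRUE, also return the simulated current trace
#'   sampled at \code{trace_dt_ms} over the whole sweep.
#' @param trace_dt_ms trace sampling interval, ms (default 0.05 = 20 kHz).
#' @return list with \code{peaks} (named vector of signed peak currents,
#'   nA, inward negative, ordered by pulse index), \code{final_occupancy},
#'   and optionally \code{trace} (data frame time_ms, current_nA).
#' @export
simulate_sweep <- function(channel, drug, protocol, conc,
                           init = NULL, peak_dt_ms = 0.01,
                           return_trace = FALSE, trace_dt_ms = 0.05) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  segs <- protocol$segments
  if (!any(segs$role == "test_pulse")) stop("protocol has no test pulses")
  dcache <- new.env(parent = emptyenv())
  dec_for <- function(V) {
    key <- format(V, digits = 12)
    if (is.null(dcache[[key]]))
      dcache[[key]] <- qdecomp(build_rate_matrix(channel, drug, V, conc))
    dcache[[key]]
  }
  if (is.null(init)) {
    Qh <- build_rate_matrix(channel, drug, protocol$config$holding_mV, 0)
    init <- equilibrium_occupancy(Qh)
  }
  p <- init
  g <- channel$conductance_scale
  peaks <- rep(NA_real_, 17)
  tr_t <- list(); tr_i <- list(); t_off <- 0
  for (k in seq_len(nrow(segs))) {
    dur <- segs$duration_ms[k]
    dec <- dec_for(segs$voltage_mV[k])
    is_test <- segs$role[k] == "test_pulse"
    if (is_test || return_trace) {
      dt <- if (is_test) peak_dt_ms else trace_dt_ms
      times <- unique(c(seq(0, dur, by = dt), dur))
      P <- occupancy_path(p, dec, times)
      occ <- conducting_occupancy(P, channel, drug)
      if (is_test) peaks[segs$pulse_index[k]] <- -g * max(occ)
      if (return_trace) {
        keep <- times < dur | k == nrow(segs)
        tr_t[[k]] <- t_off + times[keep]
        tr_i[[k]] <- -g * occ[keep]
      }
      p <- P[length(times), ]
    } else {
      p <- occupancy_path(p, dec, dur)[1, ]
    }
    t_off <- t_off + dur
  }
  names(p) <- c(channel$states, paste0(channel$states, ":B"))
  out <- list(peaks = stats::setNames(peaks, 1:17), final_occupancy = p)
  if (return_trace)
    out$trace <- data.frame(time_ms = unlist(tr_t), current_nA = unlist(tr_i))
  out
}

#' Perfusion schedule constructor
#'
#' @param n_sweeps integer vector: number of sweeps in each block.
#' @param conc_uM target applied concentration of each block, uM.
#' @return data frame with one row per block.
#' @export
perfusion_schedule <- function(n_sweeps, conc_uM) {
  stopifnot(length(n_sweeps) == length(conc_uM), length(n_sweeps) >= 1,
            all(n_sweeps >= 1))
  if (any(conc_uM < 0)) stop("negative target concentration")
  data.frame(block = seq_along(n_sweeps), n_sweeps = as.integer(n_sweeps),
             conc_uM = conc_uM)
}

#' Simulate a full perfusion experiment
#'
#' Runs consecutive sweeps at 1/sweep-period frequency while the applied
#' concentration relaxes exponentially (time constant
#' \code{drug$perfusion_tau_s}) toward the target of each schedule block,
#' emulating solution exchange in the recording chamber. Per-pulse peak
#' currents are perturbed by multiplicative Gaussian noise and an optional
#' linear rundown. The simulation is fully deterministic for a fixed seed.
#'
#' @param channel a [channel_model()].
#' @param drug a [compound_mechanism()].
#' @param protocol a \code{voltage_protocol}.
#' @param schedule a [perfusion_schedule()].
#' @param noise_sd multiplicative Gaussian noise s.d. (fraction of peak).
#' @param rundown_per_sweep fractional amplitude loss per sweep (default 0).
#' @param seed integer seed (mandatory: all stochastic runs are seeded).
#' @param keep_traces if TRUE, store the full current trace of every sweep.
#' @return object of class \code{simulated_experiment}: list with
#'   \code{amplitudes} (data frame sweep_index, time_s, pulse_index,
#'   amplitude_nA, conc_uM, target_conc_uM, block), \code{schedule},
#'   \code{protocol}, \code{ground_truth}, \code{seed}, and optionally
#'   \code{traces}.
#' @export
simulate_experiment <- function(channel, drug, protocol, schedule,
                                noise_sd = 0.02, rundown_per_sweep = 0,
                                seed, keep_traces = FALSE) {
  stopifnot(inherits(channel, "channel_model"),
            inherits(drug, "compound_mechanism"),
            is.data.frame(schedule), nrow(schedule) >= 1)
  if (missing(seed)) stop("a seed is mandatory for stochastic simulations")
  if (any(schedule$conc_uM < 0)) stop("negative target concentration")
  stopifnot(noise_sd >= 0, rundown_per_sweep >= 0)
  set.seed(as.integer(seed))

  period_s <- protocol$sweep_period_ms / 1000
  decay <- exp(-period_s / drug$perfusion_tau_s)
  n_total <- sum(schedule$n_sweeps)
  targets <- rep(schedule$conc_uM, schedule$n_sweeps)
  blocks <- rep(schedule$block, schedule$n_sweeps)
  conc <- numeric(n_total)
  c_now <- 0
  for (s in seq_len(n_total)) {
    conc[s] <- c_now
    c_now <- targets[s] + (c_now - targets[s]) * decay
  }

  Qh <- build_rate_matrix(channel, drug, protocol$config$holding_mV, 0)
  p <- equilibrium_occupancy(Qh)
  rows <- vector("list", n_total)
  traces <- if (keep_traces) vector("list", n_total) else NULL
  for (s in seq_len(n_total)) {
    sw <- simulate_sweep(channel, drug, protocol, conc[s], init = p,
                         return_trace = keep_traces)
    p <- sw$final_occupancy
    noisy <- sw$peaks * (1 + stats::rnorm(17, 0, noise_sd)) *
      (1 - rundown_per_sweep)^(s - 1)
    rows[[s]] <- data.frame(sweep_index = s, time_s = (s - 1) * period_s,
                            pulse_index = 1:17, amplitude_nA = unname(noisy),
                            conc_uM = conc[s], target_conc_uM = targets[s],
                            block = blocks[s])
    if (keep_traces) traces[[s]] <- sw$trace
  }
  out <- list(amplitudes = do.call(rbind, rows),
              schedule = schedule, protocol = protocol,
              ground_truth = ground_truth(channel, drug, noise_sd,
                                          rundown_per_sweep, seed),
              seed = as.integer(seed))
  if (keep_traces) out$traces <- traces
  class(out) <- "simulated_experiment"
  out
}

ground_truth <- function(channel, drug, noise_sd, rundown_per_sweep, seed) {
  list(compound = drug$name,
       k_on_per_uM_ms = drug$k_on,
       K_R_uM = drug$K_R,
       K_I_uM = drug$K_I,
       K_ratio = drug$K_R / drug$K_I,
       unbinding_tau_rest_ms = 1 / (drug$k_on * drug$K_R),
       unbinding_tau_inact_ms = 1 / (drug$k_on * drug$K_I),
       perfusion_tau_s = drug$perfusion_tau_s,
       access_factors = as.list(drug$access_factors),
       inactivated_states = drug$inactivated_states,
       bound_conducting = drug$bound_conducting,
       conductance_scale_nA = channel$conductance_scale,
       noise_sd = noise_sd, rundown_per_sweep = rundown_per_sweep,
       seed = as.integer(seed))
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("<simulated_experiment> %s: %d sweeps, %d blocks, seed %d\n",
              x$ground_truth$compound, max(x$amplitudes$sweep_index),
              nrow(x$schedule), x$seed))
  invisible(x)
}

#' Write the ground-truth sidecar of a simulated experiment
#'
#' @param experiment a \code{simulated_experiment}.
#' @param path output path (JSON).
#' @export
write_ground_truth <- function(experiment, path) {
  jsonlite::write_json(experiment$ground_truth, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
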