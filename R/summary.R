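# Compound-level, concentration-independent descriptors ------------------

#' Fraction of channels inactivated at the depolarized holding potential
#'
#' Estimated from drug-free sweeps as \code{h = 1 - |peak #17| / |peak #1|}
#' averaged over a control window: pulse #17 is delivered from the most
#' depolarized holding level while pulse #1 is fully rested, so their ratio
#' measures steady-state availability.
#'
#' @param amplitudes an \code{amplitude_series}.
#' @param application which application's control window to use (default 1,
#'   i.e. the window right before the first drug perfusion).
#' @param min_sweeps minimum number of control sweeps required.
#' @return h in [0, 1].
#' @export
fraction_inactivated <- function(amplitudes, application = 1, min_sweeps = 5) {
  ctl <- amplitudes[amplitudes$phase == paste0("control_", application), ]
  ns <- length(unique(ctl$sweep_index))
  if (ns < min_sweeps)
    stop("need at least ", min_sweeps, " control sweeps, got ", ns)
  a1 <- mean(abs(ctl$amplitude_nA[ctl$pulse_index == 1]))
  a17 <- mean(abs(ctl$amplitude_nA[ctl$pulse_index == 17]))
  if (a1 == 0) stop("zero control amplitude at pulse #1")
  min(1, max(0, 1 - a17 / a1))
}

#' Resting- and inactivated-state affinity estimates
#'
#' \code{K_R} is approximated by the IC50 of the fully rested pulse #1.
#' The IC50 of pulse #17 (\code{K_app}) reflects a mixed population of
#' resting and inactivated channels at the depolarized holding potential;
#' the inactivated-state affinity is recovered from the classical
#' mixed-population binding identity
#' \code{1/K_app = (1 - h)/K_R + h/K_I}, i.e.
#' \code{K_I = h / (1/K_app - (1 - h)/K_R)},
#' where \code{h} is the inactivated fraction at the depolarized holding
#' potential, measured as one minus the #17/#1 control amplitude ratio
#' (see [fraction_inactivated()]). Each state class contributes to the
#' apparent affinity in proportion to its occupancy: in the limits,
#' \code{h = 1} collapses to \code{K_I = K_app} (all channels inactivated),
#' \code{K_app = K_R} forces \code{K_I = K_R} for any \code{h > 0}, and at
#' \code{h = 0} the inactivated affinity is unidentifiable (no inactivated
#' channels contribute) and an error is raised.
#'
#' @param eip_curves an \code{eip_curves} object (or a list with numeric
#'   elements \code{K_R} and \code{K_app} for direct use).
#' @param h inactivated fraction at the depolarized holding potential,
#'   in [0, 1).
#' @return list with \code{K_R}, \code{K_app}, \code{K_I}, \code{ratio}
#'   (= K_R/K_I) and \code{flag} (\code{"ok"} or
#'   \code{"inconsistent_estimates"} when the denominator is not positive).
#' @export
estimate_affinities <- function(eip_curves, h) {
  stopifnot(is.numeric(h), length(h) == 1, h <= 1)
  if (h <= 0)
    stop("h = 0: K_I is unidentifiable (no inactivated channels at -70 mV)")
  if (inherits(eip_curves, "eip_curves")) {
    K_R <- eip_ic50(eip_curves, 1)
    K_app <- eip_ic50(eip_curves, 17)
  } else {
    K_R <- eip_curves$K_R; K_app <- eip_curves$K_app
    stopifnot(is.numeric(K_R), is.numeric(K_app))
  }
  denom <- 1 / K_app - (1 - h) / K_R
  if (denom <= 0)
    return(list(K_R = K_R, K_app = K_app, K_I = NA_real_, ratio = NA_real_,
                flag = "inconsistent_estimates"))
  K_I <- h / denom
  list(K_R = K_R, K_app = K_app, K_I = K_I, ratio = K_R / K_I, flag = "ok")
}

#' Apparent affinity predicted from state affinities and availability
#'
#' Forward form of the mixed-population binding identity, useful for
#' round-trip checks: \code{K_app = 1 / ((1 - h)/K_R + h/K_I)}.
#'
#' @param K_R,K_I state dissociation constants, uM.
#' @param h inactivated fraction.
#' @return K_app, uM.
#' @export
apparent_affinity <- function(K_R, K_I, h) 1 / ((1 - h) / K_R + h / K_I)

#' Macroscopic offset time constant from washout amplitudes
#'
#' Fits a single exponential \code{A(t) = A_inf - dA * exp(-t / tau)} to
#' the recovery of peak amplitude after drug washout (second-scale
#' "macro-dynamics", dominated by solution exchange).
#'
#' @param washout data frame with columns \code{time_s} and
#'   \code{amplitude_nA} (signed or absolute), or an \code{amplitude_series}
#'   plus \code{washout_block}/\code{pulse_index} to select the sweeps.
#' @param pulse_index pulse whose amplitude is followed (default 17, the
#'   most strongly inhibited one).
#' @param washout_block schedule block index of the washout period (only
#'   when \code{washout} is a full amplitude table with a \code{block}
#'   column).
#' @param min_sweeps minimum number of washout sweeps.
#' @return list with \code{tau_s}, \code{plateau_nA}, \code{delta_nA} and
#'   \code{flag} (\code{"ok"} or \code{"non_recovering"}).
#' @export
macro_offset_tau <- function(washout, pulse_index = 17, washout_block = NULL,
                             min_sweeps = 10) {
  if (!is.null(washout_block)) {
    stopifnot("block" %in% names(washout))
    washout <- washout[washout$block == washout_block &
                         washout$pulse_index == pulse_index,
                       c("time_s", "amplitude_nA")]
  }
  stopifnot(all(c("time_s", "amplitude_nA") %in% names(washout)))
  if (nrow(washout) < min_sweeps)
    stop("need at least ", min_sweeps, " washout sweeps, got ", nrow(washout))
  t <- washout$time_s - min(washout$time_s)
  y <- abs(washout$amplitude_nA)
  half <- length(y) %/% 2
  if (mean(y[seq_len(half)]) >= mean(y[(half + 1):length(y)]) ||
      stats::sd(y) == 0)
    return(list(tau_s = NA_real_, plateau_nA = NA_real_, delta_nA = NA_real_,
                flag = "non_recovering"))
  tau0 <- max(diff(range(t)) / 5, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Ainf - dA * exp(-t / tau),
                      start = list(Ainf = max(y), dA = max(y) - min(y),
                                   tau = tau0),
                      lower = c(Ainf = 0, dA = 0, tau = 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_s = NA_real_, plateau_nA = NA_real_, delta_nA = NA_real_,
                flag = "non_recovering"))
  cf <- stats::coef(fit)
  flag <- if (cf["tau"] > 2 * diff(range(t))) "poorly_constrained" else "ok"
  list(tau_s = unname(cf["tau"]), plateau_nA = unname(cf["Ainf"]),
       delta_nA = unname(cf["dA"]), flag = flag)
}

#' Time range over which effective inhibitor potency changes
#'
#' Micro-onset/offset kinetics cannot usually be summarized by a single
#' exponential; instead the EIP-vs-time curve of a section (SDO or RFI) is
#' reduced to the time interval over which the bulk of the potency change
#' happens: the curve's cumulative progress in log(IC50), made monotone, is
#' interpolated in log-time at the \code{lo} and \code{hi} fractions of its
#' total span. The reported range is additionally snapped outward to the
#' sampled-duration grid for table-style output; raw interpolated values
#' are always returned as well.
#'
#' @param curve one section of an \code{eip_curves} object (time-valued
#'   x axis: SDO or RFI rows), or any data frame with \code{x_value} (ms)
#'   and \code{ic50_uM} columns.
#' @param lo,hi progress fractions delimiting the range.
#' @param min_fold minimum total IC50 fold-change below which the curve is
#'   flagged flat (\code{"no detectable micro-dynamics"}).
#' @param snap_grid durations (ms) to which the reported range is snapped.
#' @return list with \code{t_lo_ms}, \code{t_hi_ms} (interpolated),
#'   \code{snapped} (length-2 vector) and \code{flag}.
#' @export
micro_range <- function(curve, lo = 0.1, hi = 0.9, min_fold = 1.5,
                        snap_grid = c(0.1, 1, 2, 4, 10, 100, 500, 1000)) {
  stopifnot(all(c("x_value", "ic50_uM") %in% names(curve)))
  curve <- curve[order(curve$x_value), ]
  x <- curve$x_value; y <- log(curve$ic50_uM)
  if (length(x) < 3) stop("micro_range needs at least 3 points")
  if (any(x <= 0)) stop("micro_range requires a positive time axis")
  span <- max(y) - min(y)
  if (span < log(min_fold))
    return(list(t_lo_ms = NA_real_, t_hi_ms = NA_real_,
                snapped = c(NA_real_, NA_real_),
                flag = "no detectable micro-dynamics"))
  prog <- abs(y - y[1]) / abs(y[length(y)] - y[1])
  prog <- cummax(pmin(1, prog))           # monotone cumulative progress
  lx <- log(x)
  cross <- function(f) {
    if (prog[1] >= f) return(x[1])
    i <- min(which(prog >= f))
    x0 <- lx[i - 1]; x1 <- lx[i]; p0 <- prog[i - 1]; p1 <- prog[i]
    exp(x0 + (f - p0) / (p1 - p0) * (x1 - x0))
  }
  t_lo <- cross(lo); t_hi <- cross(hi)
  snap <- c(max(snap_grid[snap_grid <= t_lo + 1e-12], min(snap_grid)),
            min(snap_grid[snap_grid >= t_hi - 1e-12], max(snap_grid)))
  list(t_lo_ms = t_lo, t_hi_ms = t_hi, snapped = snap, flag = "ok")
}

#' Concentration-independent summary of one measurement
#'
#' Bundles all compound-level descriptors derived from a single measurement
#' (one cell ensemble): state affinities, their ratio, the macroscopic
#' washout time constant and the micro-onset/offset ranges.
#'
#' @param eip_curves an \code{eip_curves} object for the measurement.
#' @param h inactivated fraction from [fraction_inactivated()].
#' @param washout optional washout amplitude data for [macro_offset_tau()].
#' @param measurement_id label.
#' @return object of class \code{compound_summary} (a list).
#' @export
compound_summary <- function(eip_curves, h, washout = NULL,
                             measurement_id = "m1") {
  aff <- estimate_affinities(eip_curves, h)
  onset <- micro_range(eip_section(eip_curves, "SDO"))
  offset <- micro_range(eip_section(eip_curves, "RFI"))
  tau <- if (!is.null(washout)) macro_offset_tau(washout)
         else list(tau_s = NA_real_, flag = "not_measured")
  structure(list(measurement_id = measurement_id,
                 h = h,
                 K_R_uM = aff$K_R, K_app_uM = aff$K_app, K_I_uM = aff$K_I,
                 K_ratio = aff$ratio, affinity_flag = aff$flag,
                 ic50_1_uM = eip_ic50(eip_curves, 1),
                 ic50_5_uM = eip_ic50(eip_curves, 5),
                 ic50_7_uM = eip_ic50(eip_curves, 7),
                 ic50_17_uM = eip_ic50(eip_curves, 17),
                 tau_macro_off_s = tau$tau_s, tau_flag = tau$flag,
                 micro_onset_range_ms = onset$snapped,
                 micro_onset_flag = onset$flag,
                 micro_offset_range_ms = offset$snapped,
                 micro_offset_flag = offset$flag),
            class = "compound_summary")
}

#' @export
print.compound_summary <- function(x, ...) {
  cat(sprintf("<compound_summary> %s\n", x$measurement_id))
  cat(sprintf("  K_R = %.4g uM, K_I = %.4g uM (K_R/K_I = %.3g), h = %.3g\n",
              x$K_R_uM, x$K_I_uM, x$K_ratio, x$h))
  cat(sprintf("  macro-offset tau = %.3g s [%s]\n", x$tau_macro_off_s,
              x$tau_flag))
  cat(sprintf("  micro-onset %g-%g ms [%s], micro-offset %g-%g ms [%s]\n",
              x$micro_onset_range_ms[1], x$micro_onset_range_ms[2],
              x$micro_onset_flag,
              x$micro_offset_range_ms[1], x$micro_offset_range_ms[2],
              x$micro_offset_flag))
  invisible(x)
}

#' Tabulate compound summaries in report shape
#'
#' One column per compound/measurement group, rows for the landmark IC50s,
#' affinities and kinetic descriptors.
#'
#' @param summaries named list of \code{compound_summary} objects.
#' @return data frame with a \code{parameter} column and one column per
#'   summary.
#' @export
summary_table <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  fmt_range <- function(r) sprintf("%g-%g", r[1], r[2])
  cols <- lapply(summaries, function(s) c(
    `IC50 #1 (est. K_R) (uM)` = sprintf("%.4g", s$ic50_1_uM),
    `IC50 #5 (uM)` = sprintf("%.4g", s$ic50_5_uM),
    `IC50 #7 (uM)` = sprintf("%.4g", s$ic50_7_uM),
    `IC50 #17 (-70 mV) (uM)` = sprintf("%.4g", s$ic50_17_uM),
    `K_I (calculated) (uM)` = sprintf("%.4g", s$K_I_uM),
    `K_R/K_I ratio` = sprintf("%.3g", s$K_ratio),
    `macro-offset tau (s)` = sprintf("%.3g", s$tau_macro_off_s),
    `micro-onset range (ms)` = fmt_range(s$micro_onset_range_ms),
    `micro-offset range (ms)` = fmt_range(s$micro_offset_range_ms)))
  out <- data.frame(parameter = names(cols[[1]]), stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
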