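# Raw-trace processing: blanking, leak subtraction, peak extraction ------

#' Extract per-pulse peak currents from a sweep trace
#'
#' For each of the 17 test pulses the search window starts \code{blank_ms}
#' after the voltage step (capacitive-artifact blanking) and ends at the
#' pulse end. With \code{leak_mode = "baseline_linear"} a straight line is
#' fitted to the samples of the segment immediately preceding the pulse
#' (excluding its own first \code{blank_ms}) and extrapolated under the
#' pulse before the extremum is taken, removing linear-in-time leak and
#' offset. The returned peak is signed: the most negative value, matching
#' the inward sodium-current convention.
#'
#' @param trace data frame with columns \code{time_ms} and \code{current_nA}
#'   on a uniform grid covering all test pulses.
#' @param protocol the \code{voltage_protocol} that generated the sweep.
#' @param blank_ms artifact blanking after each voltage step, ms.
#' @param leak_mode \code{"baseline_linear"} or \code{"none"}.
#' @return named numeric vector of 17 signed peak amplitudes (nA).
#' @export
extract_peaks <- function(trace, protocol, blank_ms = 0.2,
                          leak_mode = c("baseline_linear", "none")) {
  leak_mode <- match.arg(leak_mode)
  stopifnot(is.data.frame(trace),
            all(c("time_ms", "current_nA") %in% names(trace)),
            blank_ms >= 0)
  if (blank_ms >= protocol$config$test_width_ms)
    stop("blanking window must be shorter than the test-pulse width")
  segs <- protocol$segments
  starts <- cumsum(c(0, segs$duration_ms))[seq_len(nrow(segs))]
  tt <- trace$time_ms; ii <- trace$current_nA
  peaks <- rep(NA_real_, 17)
  for (k in which(segs$role == "test_pulse")) {
    w0 <- starts[k] + blank_ms; w1 <- starts[k] + segs$duration_ms[k]
    sel <- tt >= w0 & tt <= w1
    if (sum(sel) < 1)
      stop("no samples in the window of pulse #", segs$pulse_index[k])
    y <- ii[sel]
    if (leak_mode == "baseline_linear") {
      if (k > 1) {
        b0 <- starts[k - 1] + blank_ms; b1 <- starts[k]
        bsel <- tt >= b0 & tt < b1
        if (sum(bsel) < 2) {     # very short gap: reach one segment further back
          b0 <- if (k > 2) starts[k - 2] + blank_ms else 0
          bsel <- tt >= b0 & tt < b1
        }
      } else {
        # first pulse opens the sweep: in gap-free recordings its baseline
        # is the terminal holding period of the (previous) sweep
        b0 <- starts[nrow(segs)] + blank_ms
        bsel <- tt >= b0
      }
      if (sum(bsel) >= 2) {
        fit <- stats::lm.fit(cbind(1, tt[bsel]), ii[bsel])
        y <- y - (fit$coefficients[1] + fit$coefficients[2] * tt[sel])
      } else {
        y <- y - mean(ii[bsel])
      }
    }
    peaks[segs$pulse_index[k]] <- min(y)
  }
  stats::setNames(peaks, 1:17)
}

#' Build an amplitude series from traces or simulator output
#'
#' Convenience wrapper: applies [extract_peaks()] to each sweep trace of a
#' simulated experiment and returns the long-format amplitude table the
#' analysis pipeline consumes.
#'
#' @param experiment a \code{simulated_experiment} produced with
#'   \code{keep_traces = TRUE}.
#' @param ... passed to [extract_peaks()].
#' @return data frame like \code{experiment$amplitudes} but with amplitudes
#'   re-measured from the traces.
#' @export
peaks_from_traces <- function(experiment, ...) {
  stopifnot(inherits(experiment, "simulated_experiment"),
            !is.null(experiment$traces))
  amps <- experiment$amplitudes
  out <- lapply(seq_along(experiment$traces), function(s) {
    pk <- extract_peaks(experiment$traces[[s]], experiment$protocol, ...)
    a <- amps[amps$sweep_index == s, ]
    a <- a[order(a$pulse_index), ]
    a$amplitude_nA <- unname(pk)
    a
  })
  do.call(rbind, out)
}

#' Annotate sweeps with control / drug analysis phases
#'
#' Tags the sweeps that enter the downstream ratio analysis: for each drug
#' application (schedule block with positive target concentration) the last
#' \code{control_window_s} of the immediately preceding drug-free block
#' become \code{control_k}, and the last \code{drug_window_s} of the
#' application become \code{drug_k}. Each application is therefore
#' normalized to its own freshly measured control, which cancels slow
#' amplitude drift.
#'
#' @param amplitudes amplitude table (columns sweep_index, time_s,
#'   pulse_index, amplitude_nA, block, target_conc_uM) as produced by
#'   [simulate_experiment()] or read from file.
#' @param schedule the [perfusion_schedule()] of the experiment.
#' @param control_window_s,drug_window_s window lengths, s.
#' @return an \code{amplitude_series}: the input with an added \code{phase}
#'   column (\code{control_k}/\code{drug_k}/\code{unused}) and an
#'   \code{applications} attribute mapping application index to target
#'   concentration.
#' @export
annotate_phases <- function(amplitudes, schedule,
                            control_window_s = 5, drug_window_s = 5) {
  stopifnot(is.data.frame(amplitudes), is.data.frame(schedule))
  if (nrow(schedule) == 0) stop("empty perfusion schedule")
  stopifnot(control_window_s > 0, drug_window_s > 0)
  n_sweeps <- max(amplitudes$sweep_index)
  if (sum(schedule$n_sweeps) != n_sweeps)
    stop(sprintf("schedule covers %d sweeps but amplitudes contain %d",
                 sum(schedule$n_sweeps), n_sweeps))
  period_s <- if (n_sweeps > 1)
    diff(sort(unique(amplitudes$time_s)))[1] else 1
  ctrl_n <- max(1L, round(control_window_s / period_s))
  drug_n <- max(1L, round(drug_window_s / period_s))

  ends <- cumsum(schedule$n_sweeps)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  phase <- rep("unused", n_sweeps)
  app <- 0L
  app_conc <- numeric(0)
  for (b in seq_len(nrow(schedule))) {
    if (schedule$conc_uM[b] <= 0) next
    if (b == 1 || schedule$conc_uM[b - 1] > 0)
      stop("each application must be preceded by a drug-free block")
    app <- app + 1L
    app_conc[app] <- schedule$conc_uM[b]
    if (drug_n > schedule$n_sweeps[b])
      stop("drug window longer than application block ", b)
    if (ctrl_n > schedule$n_sweeps[b - 1])
      stop("control window longer than the block preceding application ", app)
    csw <- (ends[b - 1] - ctrl_n + 1L):ends[b - 1]
    dsw <- (ends[b] - drug_n + 1L):ends[b]
    phase[csw] <- paste0("control_", app)
    phase[dsw] <- paste0("drug_", app)
  }
  if (app == 0L) stop("schedule contains no drug application")
  out <- amplitudes
  out$phase <- phase[out$sweep_index]
  attr(out, "applications") <- data.frame(application = seq_len(app),
                                          conc_uM = app_conc)
  class(out) <- c("amplitude_series", class(out))
  out
}

#' Read / write amplitude tables
#'
#' The on-disk format is plain comma-separated text with the fixed header
#' \code{sweep_index,time_s,pulse_index,amplitude_nA,phase,conc_uM} (plus
#' any extra columns present), readable by any spreadsheet or language.
#'
#' @param amplitudes an amplitude table / \code{amplitude_series}.
#' @param path file path.
#' @export
write_amplitudes <- function(amplitudes, path) {
  lead <- intersect(c("sweep_index", "time_s", "pulse_index", "amplitude_nA",
                      "phase", "conc_uM"), names(amplitudes))
  df <- amplitudes[, c(lead, setdiff(names(amplitudes), lead)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_amplitudes
#' @export
read_amplitudes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sweep_index", "time_s", "pulse_index", "amplitude_nA")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("amplitude table misses column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!setequal(df$pulse_index, 1:17))
    stop("amplitude table must contain pulse indices 1..17")
  df
}
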