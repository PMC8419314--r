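# Voltage-clamp protocol representation ----------------------------------
#
# A protocol is an ordered list of piecewise-constant voltage segments plus
# a condition map that records, for each of the 17 test pulses, which
# analysis section(s) it belongs to (SDO / RFI / SSI) and the x-axis value
# used when plotting effective inhibitor potency against that section's
# abscissa.

#' Configuration for the 17-pulse voltage protocol
#'
#' Returns the default configuration of the composite 17-pulse protocol used
#' throughout the package, optionally overriding individual fields. The
#' protocol interleaves three classical sodium-channel assays into a single
#' 1 s sweep repeated at 1 Hz:
#' \describe{
#'   \item{SDO}{state-dependent onset: test pulses preceded by depolarizing
#'     conditioning prepulses of increasing duration, each separated from the
#'     test pulse by a short hyperpolarizing gap.}
#'   \item{RFI}{recovery from inactivation: a train of test pulses separated
#'     by hyperpolarizing gaps of increasing duration.}
#'   \item{SSI}{steady-state inactivation: test pulses delivered after
#'     equilibration at progressively depolarized holding potentials.}
#' }
#'
#' @param holding_mV holding (hyperpolarized) potential, mV.
#' @param test_mV test/conditioning depolarization potential, mV.
#' @param test_width_ms width of every test pulse, ms.
#' @param sdo_durations_ms strictly increasing conditioning-prepulse
#'   durations for pulses #2--#5, ms.
#' @param sdo_gap_ms hyperpolarizing gap between each conditioning prepulse
#'   and its test pulse, ms.
#' @param sdo_recovery_ms extra holding-time inserted before each
#'   conditioning prepulse (0 keeps the sweep inside its 1 s budget).
#' @param rfi_gap_map named numeric vector mapping pulse index (as name) to
#'   the duration, ms, of the hyperpolarizing gap that precedes it. The
#'   default honors the convention that pulse #7 follows the 1 ms gap.
#' @param rested_gap_ms nominal hyperpolarized interval preceding pulse #1
#'   (the inter-sweep holding period); used as pulse #1's RFI x-value.
#' @param ssi_levels_mV holding potentials probed by the SSI section, one
#'   per pulse #12--#17, most negative first. Pulse #12 doubles as the most
#'   hyperpolarized SSI point and needs no extra equilibration segment.
#' @param ssi_equil_ms equilibration time spent at each SSI level before its
#'   test pulse, ms.
#' @param sweep_period_ms sweep repetition period, ms (1 Hz stimulation).
#' @return a list of class \code{protocol_config}.
#' @seealso [build_seventeen_pulse_protocol()]
#' @export
protocol_config <- function(holding_mV = -130,
                            test_mV = -10,
                            test_width_ms = 5,
                            sdo_durations_ms = c(2.5, 7.5, 22.5, 67.5),
                            sdo_gap_ms = 2.5,
                            sdo_recovery_ms = 0,
                            rfi_gap_map = c(`6` = 64, `7` = 1, `8` = 2, `9` = 4,
                                            `10` = 8, `11` = 16, `12` = 32),
                            rested_gap_ms = 498,
                            ssi_levels_mV = c(-130, -110, -100, -90, -80, -70),
                            ssi_equil_ms = 50,
                            sweep_period_ms = 1000) {
  cfg <- list(holding_mV = holding_mV, test_mV = test_mV,
              test_width_ms = test_width_ms,
              sdo_durations_ms = sdo_durations_ms, sdo_gap_ms = sdo_gap_ms,
              sdo_recovery_ms = sdo_recovery_ms,
              rfi_gap_map = rfi_gap_map, rested_gap_ms = rested_gap_ms,
              ssi_levels_mV = ssi_levels_mV, ssi_equil_ms = ssi_equil_ms,
              sweep_period_ms = sweep_period_ms)
  class(cfg) <- "protocol_config"
  validate_protocol_config(cfg)
  cfg
}

validate_protocol_config <- function(cfg) {
  stopifnot(is.numeric(cfg$test_width_ms), cfg$test_width_ms > 0,
            cfg$sweep_period_ms > 0, cfg$sdo_gap_ms > 0,
            cfg$sdo_recovery_ms >= 0, cfg$ssi_equil_ms > 0,
            cfg$rested_gap_ms > 0)
  if (any(cfg$sdo_durations_ms <= 0) || is.unsorted(cfg$sdo_durations_ms, strictly = TRUE))
    stop("SDO conditioning durations must be positive and strictly increasing")
  if (length(cfg$sdo_durations_ms) != 4L)
    stop("expected 4 SDO conditioning durations (pulses #2-#5)")
  if (is.null(names(cfg$rfi_gap_map)) ||
      !setequal(names(cfg$rfi_gap_map), as.character(6:12)))
    stop("rfi_gap_map must be named with pulse indices 6..12")
  if (any(cfg$rfi_gap_map <= 0)) stop("RFI gap durations must be positive")
  if (length(cfg$ssi_levels_mV) != 6L)
    stop("expected 6 SSI holding levels (pulses #12-#17)")
  if (is.unsorted(cfg$ssi_levels_mV, strictly = TRUE))
    stop("SSI holding levels must be strictly increasing (most negative first)")
  invisible(cfg)
}

segment <- function(duration_ms, voltage_mV, role, pulse_index = NA_integer_) {
  data.frame(duration_ms = duration_ms, voltage_mV = voltage_mV,
             role = role, pulse_index = as.integer(pulse_index),
             stringsAsFactors = FALSE)
}

#' Build the composite 17-pulse SDO/RFI/SSI protocol
#'
#' Assembles the segment table and condition map of the 17-pulse protocol
#' from a [protocol_config()]. Pulse #1 is the rested baseline (it follows
#' the long inter-sweep holding period and doubles as the longest-gap RFI
#' point); pulses #2--#5 form the SDO section, #6--#12 the RFI section, and
#' #12--#17 the SSI section (#12 is shared between RFI and SSI).
#'
#' The sweep ends with a holding segment that fills the remainder of the
#' sweep period; its length must be positive, otherwise the configuration
#' does not fit the stimulation frequency and an error is raised.
#'
#' @param config a [protocol_config()].
#' @return an object of class \code{voltage_protocol}: a list with elements
#'   \code{segments} (data frame: duration_ms, voltage_mV, role,
#'   pulse_index), \code{condition_map} (data frame: pulse_index, section,
#'   x_value, x_unit), \code{sweep_period_ms} and \code{config}.
#' @examples
#' prot <- build_seventeen_pulse_protocol(protocol_config())
#' condition_of(prot, 7)
#' @export
build_seventeen_pulse_protocol <- function(config = protocol_config()) {
  validate_protocol_config(config)
  hold <- config$holding_mV; test <- config$test_mV; tw <- config$test_width_ms
  segs <- list()
  cmap <- list()
  add_seg <- function(s) segs[[length(segs) + 1L]] <<- s
  add_cond <- function(pulse, section, x, unit)
    cmap[[length(cmap) + 1L]] <<- data.frame(pulse_index = as.integer(pulse),
                                             section = section, x_value = x,
                                             x_unit = unit,
                                             stringsAsFactors = FALSE)

  # pulse 1: rested baseline; follows the inter-sweep holding period
  add_seg(segment(tw, test, "test_pulse", 1L))
  add_cond(1L, "rested", NA_real_, "")
  add_cond(1L, "RFI", config$rested_gap_ms, "ms")

  # SDO: conditioning prepulse, fixed gap, test pulse (pulses 2-5)
  for (i in seq_along(config$sdo_durations_ms)) {
    d <- config$sdo_durations_ms[i]
    if (config$sdo_recovery_ms > 0)
      add_seg(segment(config$sdo_recovery_ms, hold, "holding"))
    add_seg(segment(d, test, "conditioning"))
    add_seg(segment(config$sdo_gap_ms, hold, "gap"))
    add_seg(segment(tw, test, "test_pulse", i + 1L))
    add_cond(i + 1L, "SDO", d, "ms")
  }

  # RFI: gap of mapped duration then test pulse, pulses 6-12 in index order
  for (p in 6:12) {
    g <- unname(config$rfi_gap_map[as.character(p)])
    add_seg(segment(g, hold, "gap"))
    add_seg(segment(tw, test, "test_pulse", as.integer(p)))
    add_cond(p, "RFI", g, "ms")
  }

  # SSI: pulse 12 doubles as the most hyperpolarized level; 13-17 get an
  # equilibration segment at their holding level before the test pulse
  add_cond(12L, "SSI", config$ssi_levels_mV[1], "mV")
  for (i in 2:6) {
    lev <- config$ssi_levels_mV[i]
    add_seg(segment(config$ssi_equil_ms, lev, "conditioning"))
    add_seg(segment(tw, test, "test_pulse", as.integer(11L + i)))
    add_cond(11L + i, "SSI", lev, "mV")
  }

  segments <- do.call(rbind, segs)
  used <- sum(segments$duration_ms)
  remainder <- config$sweep_period_ms - used
  if (remainder <= 0)
    stop(sprintf("protocol duration (%.1f ms) exceeds sweep period (%.1f ms)",
                 used, config$sweep_period_ms))
  segments <- rbind(segments, segment(remainder, hold, "holding"))
  rownames(segments) <- NULL

  prot <- list(segments = segments,
               condition_map = do.call(rbind, cmap),
               sweep_period_ms = config$sweep_period_ms,
               config = config)
  class(prot) <- "voltage_protocol"
  validate_protocol(prot)
  prot
}

validate_protocol <- function(prot) {
  segs <- prot$segments
  stopifnot(all(segs$duration_ms > 0))
  pidx <- segs$pulse_index[segs$role == "test_pulse"]
  if (anyNA(pidx) || length(unique(pidx)) != 17L)
    stop("protocol must contain exactly 17 distinct test pulses")
  if (any(!is.na(segs$pulse_index) & segs$role != "test_pulse"))
    stop("pulse_index is only allowed on test_pulse segments")
  if (sum(segs$duration_ms) > prot$sweep_period_ms + 1e-9)
    stop("segment durations exceed the sweep period")
  if (!all(1:17 %in% prot$condition_map$pulse_index))
    stop("every pulse index 1..17 must appear in the condition map")
  invisible(prot)
}

#' Section membership and plotting abscissa of a test pulse
#'
#' @param protocol a \code{voltage_protocol}.
#' @param pulse_index integer in 1..17.
#' @return data frame with one row per section the pulse belongs to
#'   (columns: pulse_index, section, x_value, x_unit).
#' @export
condition_of <- function(protocol, pulse_index) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (!is.numeric(pulse_index) || length(pulse_index) != 1L ||
      !(pulse_index %in% protocol$condition_map$pulse_index))
    stop("unknown pulse_index: ", pulse_index)
  out <- protocol$condition_map[protocol$condition_map$pulse_index == pulse_index, ]
  rownames(out) <- NULL
  out
}

#' Start and end times of every test pulse within a sweep
#'
#' @param protocol a \code{voltage_protocol}.
#' @return data frame (pulse_index, start_ms, end_ms) in time order.
#' @export
pulse_windows <- function(protocol) {
  segs <- protocol$segments
  t0 <- cumsum(c(0, segs$duration_ms))[seq_len(nrow(segs))]
  sel <- segs$role == "test_pulse"
  out <- data.frame(pulse_index = segs$pulse_index[sel],
                    start_ms = t0[sel],
                    end_ms = t0[sel] + segs$duration_ms[sel])
  out[order(out$start_ms), , drop = FALSE]
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %d segments, %d test pulses, sweep period %g ms\n",
              nrow(x$segments),
              sum(x$segments$role == "test_pulse"), x$sweep_period_ms))
  secs <- split(x$condition_map$pulse_index, x$condition_map$section)
  for (s in names(secs))
    cat(sprintf("  %-6s pulses: %s\n", s,
                paste(sort(unique(secs[[s]])), collapse = ", ")))
  invisible(x)
}

# Protocol serialization --------------------------------------------------

#' Write / read a protocol segment table
#'
#' The flat serialization is one row per segment (duration_ms, voltage_mV,
#' role, pulse_index) plus a header comment carrying the sweep period and
#' condition map; \code{read_protocol(write_protocol(p))} reproduces the
#' protocol exactly.
#'
#' @param protocol a \code{voltage_protocol}.
#' @param path file path.
#' @return \code{read_protocol} returns a \code{voltage_protocol};
#'   \code{write_protocol} returns \code{path} invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  cfg <- unclass(protocol$config)
  cfg$rfi_gap_map <- as.list(cfg$rfi_gap_map)   # keep names in YAML
  payload <- list(sweep_period_ms = protocol$sweep_period_ms,
                  config = cfg,
                  segments = protocol$segments,
                  condition_map = protocol$condition_map)
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  payload <- yaml::read_yaml(path)
  cfg <- payload$config
  cfg$rfi_gap_map <- unlist(cfg$rfi_gap_map)
  cfg$sdo_durations_ms <- as.numeric(cfg$sdo_durations_ms)
  cfg$ssi_levels_mV <- as.numeric(cfg$ssi_levels_mV)
  prot <- build_seventeen_pulse_protocol(do.call(protocol_config, cfg))
  # guard against drift between builder and serialized table
  segs <- as.data.frame(payload$segments)
  if (!isTRUE(all.equal(prot$segments$duration_ms, as.numeric(segs$duration_ms))) ||
      !isTRUE(all.equal(prot$segments$voltage_mV, as.numeric(segs$voltage_mV))))
    stop("serialized segment table does not match its own configuration")
  prot
}
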