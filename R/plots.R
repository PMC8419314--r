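# Plotting helpers (base graphics) ---------------------------------------

#' Plot effective inhibitor potency curves
#'
#' One panel per protocol section: IC50 against conditioning duration
#' (SDO), gap duration (RFI, log time axis) and holding potential (SSI),
#' the standard panel layout for EIP figures.
#'
#' @param curves an \code{eip_curves} object (or several row-bound ones;
#'   measurements are drawn as separate lines).
#' @param main overall title.
#' @export
plot_eip <- function(curves, main = "Effective inhibitor potency") {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (sec in c("SDO", "RFI", "SSI")) {
    sub <- curves[curves$section == sec, ]
    if (!nrow(sub)) next
    logx <- sec %in% c("SDO", "RFI")
    xlab <- switch(sec, SDO = "conditioning duration (ms)",
                   RFI = "gap duration (ms)", SSI = "holding (mV)")
    graphics::plot(NA, xlim = range(sub$x_value), ylim = range(sub$ic50_uM),
                   log = if (logx) "xy" else "y",
                   xlab = xlab, ylab = "IC50 (uM)", main = sec)
    for (m in unique(sub$measurement_id)) {
      s <- sub[sub$measurement_id == m, ]
      s <- s[order(s$x_value), ]
      graphics::lines(s$x_value, s$ic50_uM, type = "b", pch = 1)
    }
  }
  graphics::mtext(main, outer = TRUE, line = -1.5, cex = 0.9)
  invisible(curves)
}

#' Plot per-pulse concentration-inhibition data and fits
#'
#' @param ratio_table a [make_ratio_table()] result.
#' @param curves the matching \code{eip_curves} (for fitted parameters).
#' @param pulses which pulses to draw.
#' @export
plot_concentration_inhibition <- function(ratio_table, curves,
                                          pulses = c(1, 5, 7, 17)) {
  fits <- attr(curves, "fits")
  graphics::plot(NA, xlim = range(ratio_table$conc_uM), ylim = c(0, 1),
                 log = "x", xlab = "concentration (uM)",
                 ylab = "inhibited fraction",
                 main = "Per-pulse concentration-inhibition")
  cc <- exp(seq(log(min(ratio_table$conc_uM) / 3),
                log(max(ratio_table$conc_uM) * 3), length.out = 100))
  for (i in seq_along(pulses)) {
    p <- pulses[i]
    sub <- ratio_table[ratio_table$pulse_index == p, ]
    graphics::points(sub$conc_uM, pmax(0, 1 - sub$ratio), col = i, pch = 16)
    f <- fits[[as.character(p)]]
    if (!is.null(f))
      graphics::lines(cc, hill_inhibition(cc, f$ic50, f$nH), col = i)
  }
  graphics::legend("topleft", legend = paste0("#", pulses),
                   col = seq_along(pulses), lty = 1, bty = "n")
  invisible(ratio_table)
}

#' Plot amplitude time courses per protocol section
#'
#' Mirrors the standard amplitude-plot layout: per-pulse peak amplitude
#' against experiment time, grouped into the SDO, RFI and SSI pulse sets.
#'
#' @param amplitudes an amplitude table.
#' @param protocol the matching \code{voltage_protocol}.
#' @export
plot_amplitudes <- function(amplitudes, protocol) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  cm <- protocol$condition_map
  for (sec in c("SDO", "RFI", "SSI")) {
    ps <- sort(unique(cm$pulse_index[cm$section == sec]))
    sub <- amplitudes[amplitudes$pulse_index %in% ps, ]
    graphics::plot(NA, xlim = range(sub$time_s),
                   ylim = range(sub$amplitude_nA),
                   xlab = "time (s)", ylab = "peak (nA)", main = sec)
    for (i in seq_along(ps)) {
      s <- sub[sub$pulse_index == ps[i], ]
      graphics::lines(s$time_s, s$amplitude_nA, col = i)
    }
  }
  invisible(amplitudes)
}
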