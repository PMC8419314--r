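# EIP over a firing pattern ----------------------------------------------

interp_loglog <- function(curve, elapsed_ms) {
  x <- curve$x_value; y <- curve$ic50_uM
  o <- order(x); x <- x[o]; y <- y[o]
  if (length(x) == 1) return(rep(y, length(elapsed_ms)))
  out <- exp(stats::approx(log(x), log(y), xout = log(pmax(elapsed_ms, min(x))),
                           rule = 2)$y)
  out
}

#' Effective inhibitor potency over a firing pattern
#'
#' Translates the millisecond-scale potency dynamics measured by the SDO
#' and RFI sections into a time course of EIP during repetitive firing:
#' after each action-potential upstroke the potency follows the SDO curve
#' (onset clock restarted at zero), and after each repolarization it
#' follows the RFI curve (recovery clock restarted). Interpolation is
#' linear in log-time / log-IC50, with constant extrapolation beyond the
#' measured curve ends.
#'
#' @param sdo_curve,rfi_curve EIP sections (data frames with \code{x_value}
#'   in ms and \code{ic50_uM}), e.g. from [eip_section()].
#' @param events data frame with \code{time_ms} (strictly increasing) and
#'   \code{type} (\code{"upstroke"}/\code{"repolarization"}, alternating).
#' @param t_grid_ms evaluation times; default a 0.5 ms grid spanning the
#'   events plus one RFI curve length.
#' @return data frame (time_ms, ic50_uM, phase) of class
#'   \code{eip_overlay}.
#' @export
overlay_eip <- function(sdo_curve, rfi_curve, events, t_grid_ms = NULL) {
  stopifnot(is.data.frame(events),
            all(c("time_ms", "type") %in% names(events)),
            all(events$type %in% c("upstroke", "repolarization")))
  if (is.unsorted(events$time_ms, strictly = TRUE))
    stop("event times must be strictly increasing (overlapping events?)")
  if (nrow(events) > 1 &&
      any(events$type[-1] == events$type[-nrow(events)]))
    stop("events must alternate between upstroke and repolarization")
  if (is.null(t_grid_ms)) {
    t_end <- max(events$time_ms) +
      if (nrow(rfi_curve)) max(rfi_curve$x_value) else 100
    t_grid_ms <- seq(min(events$time_ms), t_end, by = 0.5)
  }
  idx <- findInterval(t_grid_ms, events$time_ms)
  keep <- idx >= 1
  tg <- t_grid_ms[keep]; idx <- idx[keep]
  elapsed <- tg - events$time_ms[idx]
  type <- events$type[idx]
  ic50 <- numeric(length(tg))
  up <- type == "upstroke"
  if (any(up)) ic50[up] <- interp_loglog(sdo_curve, elapsed[up])
  if (any(!up)) ic50[!up] <- interp_loglog(rfi_curve, elapsed[!up])
  structure(data.frame(time_ms = tg, ic50_uM = ic50,
                       phase = ifelse(up, "SDO", "RFI"),
                       stringsAsFactors = FALSE),
            class = c("eip_overlay", "data.frame"))
}
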