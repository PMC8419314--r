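# Effective inhibitor potency analysis -----------------------------------
#
# The core of the pipeline: drug/control amplitude ratios per pulse and
# concentration, per-pulse Hill fits, and the resulting IC50-vs-condition
# ("effective inhibitor potency", EIP) curves along the SDO, RFI and SSI
# axes. EIP is a time-resolved potency: because channels visit different
# conformations at the 17 pulses, the fitted IC50 fluctuates between the
# resting-state and inactivated-state dissociation constants.

applications_of <- function(amplitudes) {
  apps <- attr(amplitudes, "applications")
  if (!is.null(apps)) return(apps)
  if (!"phase" %in% names(amplitudes))
    stop("amplitudes must be annotated with phases (see annotate_phases)")
  drug <- amplitudes[grepl("^drug_", amplitudes$phase), ]
  if (nrow(drug) == 0) stop("no drug-phase sweeps in amplitude table")
  idx <- as.integer(sub("^drug_", "", drug$phase))
  cc <- if ("target_conc_uM" %in% names(drug)) drug$target_conc_uM else drug$conc_uM
  unique(data.frame(application = idx, conc_uM = cc))
}

#' Drug/control amplitude-ratio table
#'
#' For every application and every pulse, divides the mean absolute drug
#' peak (over the tagged drug window) by the mean absolute control peak of
#' that application's own pre-application control window.
#'
#' @param amplitudes an \code{amplitude_series} from [annotate_phases()].
#' @return data frame of class \code{ratio_table}: application, conc_uM,
#'   pulse_index, ratio, n_control, n_drug.
#' @export
make_ratio_table <- function(amplitudes) {
  apps <- applications_of(amplitudes)
  rows <- list()
  for (a in seq_len(nrow(apps))) {
    k <- apps$application[a]
    ctl <- amplitudes[amplitudes$phase == paste0("control_", k), ]
    drg <- amplitudes[amplitudes$phase == paste0("drug_", k), ]
    if (nrow(ctl) == 0 || nrow(drg) == 0)
      stop("application ", k, " lacks tagged control or drug sweeps")
    cm <- tapply(abs(ctl$amplitude_nA), ctl$pulse_index, mean)
    dm <- tapply(abs(drg$amplitude_nA), drg$pulse_index, mean)
    if (any(cm == 0))
      stop("zero control amplitude at pulse #",
           names(cm)[which(cm == 0)[1]], " (application ", k, ")")
    rows[[a]] <- data.frame(application = k, conc_uM = apps$conc_uM[a],
                            pulse_index = as.integer(names(cm)),
                            ratio = unname(dm / cm),
                            n_control = as.integer(table(ctl$pulse_index)),
                            n_drug = as.integer(table(drg$pulse_index)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ratio_table", class(out))
  out
}

#' Per-pulse Hill fits arranged as EIP curves
#'
#' Fits one concentration-inhibition Hill curve per pulse (inhibition =
#' 1 - ratio, clipped below at 0) and arranges the fitted IC50 values along
#' the plotting abscissa of each protocol section: conditioning-pulse
#' duration (SDO), preceding-gap duration (RFI) or holding potential (SSI).
#' Pulses that belong to several sections appear in each of them.
#'
#' @param ratio_table a [make_ratio_table()] result covering >= 3
#'   concentrations.
#' @param protocol the \code{voltage_protocol} that produced the data.
#' @param measurement_id label carried through to the output.
#' @param ... passed to [fit_hill()].
#' @return object of class \code{eip_curves}: data frame (measurement_id,
#'   section, pulse_index, x_value, x_unit, ic50_uM, ic50_se, nH, nH_se,
#'   flag) ordered by x within section, with the per-pulse \code{hill_fit}
#'   objects in attribute \code{fits}.
#' @export
build_eip_curves <- function(ratio_table, protocol, measurement_id = "m1", ...) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  concs <- sort(unique(ratio_table$conc_uM))
  if (length(concs) < 3)
    stop("EIP fitting requires at least 3 concentrations, got ", length(concs))
  fits <- list()
  rows <- list()
  for (p in sort(unique(ratio_table$pulse_index))) {
    sub <- ratio_table[ratio_table$pulse_index == p, ]
    fit <- fit_hill(sub$conc_uM, pmax(0, 1 - sub$ratio), ...)
    fits[[as.character(p)]] <- fit
    cond <- condition_of(protocol, p)
    cond <- cond[cond$section %in% c("SDO", "RFI", "SSI"), , drop = FALSE]
    for (r in seq_len(nrow(cond)))
      rows[[length(rows) + 1L]] <- data.frame(
        measurement_id = measurement_id, section = cond$section[r],
        pulse_index = p, x_value = cond$x_value[r], x_unit = cond$x_unit[r],
        ic50_uM = fit$ic50, ic50_se = fit$ic50_se,
        nH = fit$nH, nH_se = fit$nH_se, flag = fit$flag,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$section, c("SDO", "RFI", "SSI")), out$x_value), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("eip_curves", class(out))
  out
}

#' Extract one section of an EIP curve set
#'
#' @param curves an \code{eip_curves} object.
#' @param section \code{"SDO"}, \code{"RFI"} or \code{"SSI"}.
#' @return the section's rows, ordered by x.
#' @export
eip_section <- function(curves, section = c("SDO", "RFI", "SSI")) {
  section <- match.arg(section)
  out <- curves[curves$section == section, , drop = FALSE]
  out[order(out$x_value), , drop = FALSE]
}

#' IC50 of a given pulse from an EIP curve set
#'
#' @param curves an \code{eip_curves} object.
#' @param pulse_index pulse number, 1..17.
#' @return the fitted IC50, uM.
#' @export
eip_ic50 <- function(curves, pulse_index) {
  hit <- curves$ic50_uM[curves$pulse_index == pulse_index]
  if (!length(hit)) stop("pulse ", pulse_index, " not present in EIP curves")
  hit[1]
}

#' Write an EIP table to delimited text
#'
#' @param curves an \code{eip_curves} object.
#' @param path file path.
#' @export
write_eip_table <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
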