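# Recording quality control ----------------------------------------------

#' Exclusion rules and ensemble selection
#'
#' Applies the four standard quality criteria to per-ensemble recording
#' metrics and then selects the best remaining ensembles, ranked by mean
#' seal resistance with seal stability (smaller gradual loss) as the
#' tiebreaker. An ensemble is excluded when any of:
#' \enumerate{
#'   \item control current amplitude below \code{min_amplitude_nA};
#'   \item mean seal resistance below \code{min_seal_mohm};
#'   \item gradual seal-resistance loss above \code{max_seal_loss_pct};
#'   \item a sudden amplitude drop with a concurrent seal-resistance drop
#'     (loss of a cell from the ensemble).
#' }
#'
#' @param metrics data frame with columns \code{id},
#'   \code{control_amplitude_nA}, \code{seal_resistance_mohm},
#'   \code{seal_loss_pct}, \code{sudden_drop} (logical).
#' @param n_select number of ensembles to keep (default 6).
#' @param min_amplitude_nA,min_seal_mohm,max_seal_loss_pct thresholds.
#' @return list with \code{included} (character ids, best first),
#'   \code{excluded} (data frame id, reason), and \code{n_requested}.
#'   If fewer than \code{n_select} ensembles survive, all survivors are
#'   returned with a warning.
#' @export
qc_filter <- function(metrics, n_select = 6,
                      min_amplitude_nA = 2,
                      min_seal_mohm = 80,
                      max_seal_loss_pct = 20) {
  need <- c("id", "control_amplitude_nA", "seal_resistance_mohm",
            "seal_loss_pct", "sudden_drop")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols))
    stop("metrics table misses column(s): ",
         paste(missing_cols, collapse = ", "))
  reason <- rep(NA_character_, nrow(metrics))
  reason[is.na(reason) & abs(metrics$control_amplitude_nA) < min_amplitude_nA] <-
    sprintf("amplitude < %g nA", min_amplitude_nA)
  reason[is.na(reason) & metrics$seal_resistance_mohm < min_seal_mohm] <-
    sprintf("seal resistance < %g MOhm", min_seal_mohm)
  reason[is.na(reason) & metrics$seal_loss_pct > max_seal_loss_pct] <-
    sprintf("seal loss > %g%%", max_seal_loss_pct)
  reason[is.na(reason) & as.logical(metrics$sudden_drop)] <-
    "sudden amplitude drop with seal-resistance drop"
  surv <- metrics[is.na(reason), , drop = FALSE]
  surv <- surv[order(-surv$seal_resistance_mohm, surv$seal_loss_pct), ,
               drop = FALSE]
  if (nrow(surv) < n_select)
    warning(sprintf("only %d of the requested %d ensembles pass QC",
                    nrow(surv), n_select))
  included <- utils::head(as.character(surv$id), n_select)
  excluded <- data.frame(id = as.character(metrics$id[!is.na(reason)]),
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(included = included, excluded = excluded, n_requested = n_select)
}
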