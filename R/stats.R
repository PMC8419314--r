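# Group statistics --------------------------------------------------------

#' Geometric mean and dispersion
#'
#' Affinity-type quantities are summarized on the log scale: the geometric
#' mean together with the geometric standard deviation, plus the arithmetic
#' mean and SEM for comparability with conventional tables.
#'
#' @param x positive numeric vector (one value per measurement).
#' @return list with \code{geo_mean}, \code{geo_sd} (multiplicative),
#'   \code{mean}, \code{sem} and \code{n}.
#' @export
group_summary <- function(x) {
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 1, all(x > 0))
  n <- length(x)
  lg <- log(x)
  list(geo_mean = exp(mean(lg)),
       geo_sd = if (n > 1) exp(stats::sd(lg)) else NA_real_,
       mean = mean(x),
       sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Summarize several per-measurement compound summaries
#'
#' @param summaries list of [compound_summary()] objects for the same
#'   compound.
#' @return list with per-scalar [group_summary()] results; the K_R/K_I
#'   ratio is reported both as the mean of per-measurement ratios and as
#'   the ratio of the group geometric means.
#' @export
group_compound_summary <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  get <- function(f) vapply(summaries, function(s) s[[f]], numeric(1))
  KR <- group_summary(get("K_R_uM"))
  KI <- group_summary(get("K_I_uM"))
  list(K_R = KR, K_I = KI,
       K_ratio_per_measurement = group_summary(get("K_ratio")),
       K_ratio_of_means = KR$geo_mean / KI$geo_mean,
       h = group_summary(pmax(get("h"), .Machine$double.eps)),
       n = length(summaries))
}

# Friedman statistic on a blocks x treatments matrix of values
friedman_stat <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  cs <- colSums(r)
  # tie-corrected Friedman chi-square (matches stats::friedman.test)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 0) return(0)
  (k - 1) * (sum(cs^2) - n^2 * k * (k + 1)^2 / 4) / denom
}

#' Does effective inhibitor potency change across pulses?
#'
#' Blocked nonparametric test of whether per-pulse IC50 values differ
#' within a protocol section, with measurements (cell ensembles) as blocks.
#' The default is the asymptotic Friedman test on log(IC50); for small
#' numbers of blocks a within-block permutation variant of the same
#' statistic is available (treatment labels permuted independently inside
#' every block).
#'
#' @param ic50 numeric matrix, rows = measurements (blocks), columns =
#'   pulses/conditions; or an \code{eip_curves}-like long data frame with
#'   \code{measurement_id}, \code{pulse_index} and \code{ic50_uM}.
#' @param method \code{"friedman"} (asymptotic) or \code{"permutation"}.
#' @param n_perm number of label permutations.
#' @param seed seed for the permutation draw.
#' @return list with \code{p_value}, \code{statistic}, \code{method}.
#' @export
eip_change_test <- function(ic50, method = c("friedman", "permutation"),
                            n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  if (is.data.frame(ic50)) {
    stopifnot(all(c("measurement_id", "pulse_index", "ic50_uM") %in%
                    names(ic50)))
    ic50 <- tapply(ic50$ic50_uM,
                   list(ic50$measurement_id, ic50$pulse_index), mean)
  }
  m <- log(as.matrix(ic50))
  if (nrow(m) < 2) stop("at least 2 measurements (blocks) are required")
  if (anyNA(m)) stop("IC50 matrix must be complete")
  obs <- friedman_stat(m)
  if (method == "friedman") {
    ft <- stats::friedman.test(m)
    return(list(p_value = if (is.nan(ft$p.value)) 1 else ft$p.value,
                statistic = unname(ft$statistic), method = "friedman"))
  }
  set.seed(as.integer(seed))
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  # permuting values within a block permutes its ranks, so the tie terms
  # A = sum(r^2) and C are permutation-invariant; only colSums(r) moves
  A <- sum(r^2); C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  stat_from <- function(cs)
    if (denom <= 0) 0 else
      (k - 1) * (sum(cs^2) - n^2 * k * (k + 1)^2 / 4) / denom
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rp <- r
    for (i in seq_len(n)) rp[i, ] <- r[i, sample.int(k)]
    if (stat_from(colSums(rp)) >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (1 + n_perm), statistic = obs,
       method = "permutation")
}

#' Power to detect a standardized effect with a two-sample t-test
#'
#' Analytic power (noncentral t) for a two-sided two-sample t-test with
#' \code{n} observations per group and a true standardized effect size of
#' \code{effect_sd} standard deviations.
#'
#' @param n per-group sample size.
#' @param effect_sd standardized effect size (Cohen's d).
#' @param alpha significance level.
#' @return power in [0, 1].
#' @export
power_detectable_effect <- function(n, effect_sd, alpha = 0.05) {
  stopifnot(n >= 2, effect_sd >= 0, alpha > 0, alpha < 1)
  if (effect_sd == 0) return(alpha)
  stats::power.t.test(n = n, delta = effect_sd, sd = 1, sig.level = alpha,
                      type = "two.sample",
                      alternative = "two.sided")$power
}
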