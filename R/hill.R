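# Hill concentration-inhibition fitting ----------------------------------

#' Hill equation
#'
#' Inhibited fraction at concentration \code{cc}:
#' \code{Inh = cc^nH / (cc^nH + IC50^nH)}.
#'
#' @param cc concentration(s), uM.
#' @param ic50 half-inhibitory concentration, uM.
#' @param nH Hill coefficient.
#' @return inhibited fraction in [0, 1].
#' @export
hill_inhibition <- function(cc, ic50, nH = 1)
  stats::plogis(nH * (log(cc) - log(ic50)))

hill_start_ic50 <- function(cc, inh) {
  o <- order(cc); cc <- cc[o]; inh <- inh[o]
  cross <- which(inh[-1] >= 0.5 & inh[-length(inh)] < 0.5)
  if (length(cross)) {
    # log-interpolate the first upward half-inhibition crossing
    j <- cross[1]; i <- j + 1L
    f <- (0.5 - inh[j]) / (inh[i] - inh[j])
    return(exp(log(cc[j]) + f * (log(cc[i]) - log(cc[j]))))
  }
  exp(mean(log(range(cc))))
}

# The Hill equation is exactly linear on the logit scale:
# logit(Inh) = nH * (log cc - log IC50). A clipped logit regression gives a
# near-exact starting point even for tail-only data, where the (l50, nH)
# least-squares surface has a long shallow valley.
hill_start_logit <- function(cc, inh, nH_bounds, l_lo, l_hi) {
  z <- pmin(1 - 1e-4, pmax(1e-4, inh))
  y <- stats::qlogis(z)
  x <- log(cc)
  fit <- stats::lm.fit(cbind(1, x), y)
  nH0 <- unname(fit$coefficients[2])
  if (!is.finite(nH0) || nH0 <= 0) return(NULL)
  l0 <- -unname(fit$coefficients[1]) / nH0
  list(l50 = min(max(l0, l_lo), l_hi),
       nH = min(max(nH0, nH_bounds[1]), nH_bounds[2]))
}

#' Fit the Hill equation to per-pulse inhibition data
#'
#' Nonlinear least squares of the Hill equation in log-concentration space
#' (Levenberg-Marquardt with box constraints). Initialization takes the
#' IC50 from log-interpolation of the half-inhibition crossing and
#' \code{nH = 1}; bounds are \code{nH} in [0.3, 4] and IC50 in
#' [min(cc)/100, max(cc)*100]. Fits whose data never bracket the midpoint
#' (all inhibitions below 0.05 or above 0.95) are returned with the
#' \code{"extrapolated"} quality flag rather than failing, since tail-only
#' data still constrain the curve weakly.
#'
#' @param conc_uM concentrations, uM (>= 3 distinct values).
#' @param inhibition inhibited fractions; values outside [0, 1] are clipped.
#' @param weights optional least-squares weights (default unweighted).
#' @param nH_bounds,ic50_factor fitting bounds (see above).
#' @return object of class \code{hill_fit}: list with \code{ic50},
#'   \code{nH}, standard errors, residual norm, \code{flag} (one of
#'   \code{"ok"}, \code{"extrapolated"}, \code{"at_bound"}) and the data.
#' @export
fit_hill <- function(conc_uM, inhibition, weights = NULL,
                     nH_bounds = c(0.3, 4), ic50_factor = 100) {
  stopifnot(length(conc_uM) == length(inhibition), all(conc_uM > 0))
  if (length(unique(conc_uM)) < 3)
    stop("at least 3 distinct concentrations are required")
  inh <- pmin(1, pmax(0, inhibition))
  if (is.null(weights)) weights <- rep(1, length(inh))
  flag <- "ok"
  if (all(inh < 0.05) || all(inh > 0.95)) flag <- "extrapolated"

  l_lo <- log(min(conc_uM) / ic50_factor)
  l_hi <- log(max(conc_uM) * ic50_factor)
  lcc <- log(conc_uM)
  sse_of <- function(l, n) sum(weights * (inh - stats::plogis(n * (lcc - l)))^2)
  start <- hill_start_logit(conc_uM, inh, nH_bounds, l_lo, l_hi)
  if (is.null(start))
    start <- list(l50 = min(max(log(hill_start_ic50(conc_uM, inh)), l_lo), l_hi),
                  nH = 1)
  run_lm <- function(start) tryCatch(
    minpack.lm::nlsLM(inh ~ stats::plogis(nH * (lcc - l50)),
                      start = start, weights = weights,
                      lower = c(l50 = l_lo, nH = nH_bounds[1]),
                      upper = c(l50 = l_hi, nH = nH_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- run_lm(start)
  tol <- 1e-6
  hits_bound <- function(p)
    p["l50"] <= l_lo + tol || p["l50"] >= l_hi - tol ||
      p["nH"] <= nH_bounds[1] + tol || p["nH"] >= nH_bounds[2] - tol
  # rescue: if LM failed or slid along the shallow valley into a box bound,
  # scan a coarse (log IC50, nH) grid and refine from the best cell
  if (is.null(fit) || hits_bound(stats::coef(fit))) {
    grid <- expand.grid(l50 = seq(l_lo, l_hi, length.out = 160),
                        nH = seq(nH_bounds[1], nH_bounds[2], length.out = 40))
    sse <- mapply(sse_of, grid$l50, grid$nH)
    best <- grid[which.min(sse), ]
    fit2 <- run_lm(list(l50 = best$l50, nH = best$nH))
    if (!is.null(fit2) &&
        (is.null(fit) || sum(stats::residuals(fit2)^2) <
           sum(stats::residuals(fit)^2) + 1e-12))
      fit <- fit2
  }
  if (is.null(fit)) {
    opt <- stats::optim(unlist(start), function(par) sse_of(par[1], par[2]),
                        method = "L-BFGS-B", lower = c(l_lo, nH_bounds[1]),
                        upper = c(l_hi, nH_bounds[2]))
    pars <- c(l50 = opt$par[1], nH = opt$par[2])
    ses <- c(l50 = NA_real_, nH = NA_real_)
    rss <- opt$value
  } else {
    pars <- stats::coef(fit)
    ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
      c(l50 = NA_real_, nH = NA_real_))
    rss <- sum(stats::residuals(fit)^2)
  }
  if (hits_bound(pars) && flag == "ok") flag <- "at_bound"
  structure(list(ic50 = unname(exp(pars["l50"])),
                 nH = unname(pars["nH"]),
                 ic50_se = unname(exp(pars["l50"]) * ses["l50"]),
                 nH_se = unname(ses["nH"]),
                 rss = rss, flag = flag,
                 data = data.frame(conc_uM = conc_uM, inhibition = inh)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> IC50 = %.4g uM (se %.3g), nH = %.3g (se %.3g) [%s]\n",
              x$ic50, x$ic50_se, x$nH, x$nH_se, x$flag))
  invisible(x)
}
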