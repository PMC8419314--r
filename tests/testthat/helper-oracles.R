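# Independent oracles and shared fixture builders for the test suite.

# Brute-force Hill fit: dense grid search over (log IC50, nH), independent
# of the package's optimizer.
grid_hill_oracle <- function(cc, inh, n_l50 = 400, n_nH = 150,
                             nH_bounds = c(0.3, 4), ic50_factor = 100) {
  l_lo <- log(min(cc) / ic50_factor); l_hi <- log(max(cc) * ic50_factor)
  l50s <- seq(l_lo, l_hi, length.out = n_l50)
  nHs <- seq(nH_bounds[1], nH_bounds[2], length.out = n_nH)
  lcc <- log(cc)
  best <- c(Inf, NA, NA)
  for (n in nHs) {
    pred <- plogis(outer(l50s, lcc, function(l, x) n * (x - l)))
    sse <- rowSums(sweep(pred, 2, inh, "-")^2)
    i <- which.min(sse)
    if (sse[i] < best[1]) best <- c(sse[i], l50s[i], n)
  }
  list(ic50 = exp(best[2]), nH = best[3], sse = best[1],
       grid_step_l50 = (l_hi - l_lo) / (n_l50 - 1),
       grid_step_nH = diff(nH_bounds) / (n_nH - 1))
}

# Closed-form relaxation of a two-state chain with rates a (1->2), b (2->1).
two_state_analytic <- function(p0, a, b, t) {
  peq2 <- a / (a + b)
  p2 <- peq2 + (p0[2] - peq2) * exp(-(a + b) * t)
  c(1 - p2, p2)
}

# All unbound<->bound 4-cycles of a channel+drug generator: one per gating
# edge. Returns the clockwise and counterclockwise rate products.
binding_cycle_products <- function(Q, channel) {
  tr <- channel$transitions
  edges <- unique(t(apply(tr[, c("from", "to")], 1, sort)))
  out <- list()
  for (e in seq_len(nrow(edges))) {
    s1 <- edges[e, 1]; s2 <- edges[e, 2]
    b1 <- paste0(s1, ":B"); b2 <- paste0(s2, ":B")
    cw <- Q[s1, s2] * Q[s2, b2] * Q[b2, b1] * Q[b1, s1]
    ccw <- Q[s1, b1] * Q[b1, b2] * Q[b2, s2] * Q[s2, s1]
    out[[e]] <- c(cw = cw, ccw = ccw)
  }
  do.call(rbind, out)
}

# Small simulated experiment used by several analysis tests.
sim_experiment <- function(preset, concs = NULL, seed = 5,
                           sweeps_per_block = 25, noise_sd = 0.02,
                           mechanism = NULL) {
  mech <- if (is.null(mechanism)) mechanism_preset(preset) else mechanism
  if (is.null(concs)) concs <- preset_concentrations(preset)
  cfg <- run_config(mechanism = mech, concentrations_uM = concs,
                    sweeps_per_block = sweeps_per_block,
                    noise_sd = noise_sd, seed = seed)
  list(cfg = cfg, experiment = run_simulate(cfg))
}
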