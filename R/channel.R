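# Markov channel model and state-dependent drug binding ------------------

#' Markov gating model of a voltage-gated sodium channel
#'
#' Defines the gating states, voltage-dependent transition rates and
#' conductance scaling of the channel used by the simulator. Every rate
#' follows \code{r(V) = A * exp(V / k_V)} with \code{A} in 1/ms and
#' \code{k_V} in mV; \code{k_V = Inf} (or \code{-Inf}) gives a
#' voltage-independent rate.
#'
#' The default model ("generic fast NaV") has the topology
#' C1 = C2 = O = I with an I = C1 recovery path. Its rates are engineering
#' defaults chosen so that, at the protocol voltages, activation and
#' inactivation are complete within about 3 ms at -10 mV, recovery from
#' inactivation at -130 mV has a time constant of 3-4 ms, and the
#' steady-state availability curve has its midpoint near -72 mV (so that an
#' appreciable fraction of channels is inactivated at a -70 mV holding
#' potential).
#'
#' @param states character vector of gating state names.
#' @param transitions data frame with columns \code{from}, \code{to},
#'   \code{A} (1/ms) and \code{k_V} (mV), one row per directed transition.
#' @param open_states names of conducting state(s).
#' @param conductance_scale peak current magnitude, nA, produced by unit
#'   open-state occupancy at the test potential (lumps peak conductance and
#'   driving force).
#' @return an object of class \code{channel_model}.
#' @export
channel_model <- function(states = c("C1", "C2", "O", "I"),
                          transitions = default_gating_rates(),
                          open_states = "O",
                          conductance_scale = 10) {
  stopifnot(is.character(states), length(states) >= 2,
            all(c("from", "to", "A", "k_V") %in% names(transitions)),
            all(transitions$from %in% states),
            all(transitions$to %in% states),
            all(transitions$A >= 0),
            all(open_states %in% states),
            conductance_scale > 0)
  # connectivity of the gating graph (undirected)
  adj <- matrix(FALSE, length(states), length(states),
                dimnames = list(states, states))
  for (i in seq_len(nrow(transitions))) {
    adj[transitions$from[i], transitions$to[i]] <- TRUE
    adj[transitions$to[i], transitions$from[i]] <- TRUE
  }
  reach <- states[1]
  repeat {
    nxt <- unique(c(reach, states[colSums(adj[reach, , drop = FALSE]) > 0]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (length(reach) != length(states)) stop("gating graph is not connected")
  structure(list(states = states, transitions = transitions,
                 open_states = open_states,
                 conductance_scale = conductance_scale),
            class = "channel_model")
}

#' @rdname channel_model
#' @export
default_gating_rates <- function() {
  data.frame(
    from = c("C1", "C2", "C2", "O", "O", "I", "I", "C1"),
    to   = c("C2", "C1", "O", "C2", "I", "O", "C1", "I"),
    A    = c(30, 0.3, 30, 0.2, 4, 1e-4, 8.1e-4, 1.2),
    k_V  = c(12, -20, 12, -25, Inf, Inf, -22, 18),
    stringsAsFactors = FALSE
  )
}

#' State-dependent inhibitor mechanism (simulator ground truth)
#'
#' Describes an inhibitor by its association rate, its resting- and
#' inactivated-state dissociation constants, per-state access factors
#' (guarded-receptor accessibility) and the perfusion time constant used
#' when simulating wash-in/wash-out. The two dissociation constants express
#' the modulated-receptor picture: binding is stronger (\code{K_I < K_R})
#' when the channel is inactivated, which in turn slows recovery of bound
#' channels through microscopic reversibility of the binding cycles.
#'
#' @param k_on association rate constant, 1/(uM ms).
#' @param K_R dissociation constant for resting-class states, uM.
#' @param K_I dissociation constant for inactivated-class states, uM.
#' @param access_factors named numeric vector in [0, 1], one per gating
#'   state, multiplying \code{k_on} for binding to that state; states not
#'   named default to 1 (free access).
#' @param perfusion_tau_s exponential wash-in/wash-out time constant, s.
#' @param inactivated_states gating states assigned the high-affinity
#'   \code{K_I}; all other states use \code{K_R}.
#' @param bound_conducting if TRUE, bound open states conduct like unbound
#'   ones (pure modulated-receptor scenario); default FALSE (pure block).
#' @param name optional compound label carried through outputs.
#' @return an object of class \code{compound_mechanism}.
#' @export
compound_mechanism <- function(k_on, K_R, K_I,
                               access_factors = NULL,
                               perfusion_tau_s = 2,
                               inactivated_states = "I",
                               bound_conducting = FALSE,
                               name = "compound") {
  stopifnot(k_on > 0, K_R > 0, K_I > 0, perfusion_tau_s > 0)
  if (!is.null(access_factors)) {
    stopifnot(is.numeric(access_factors), !is.null(names(access_factors)),
              all(access_factors >= 0), all(access_factors <= 1))
  }
  structure(list(k_on = k_on, K_R = K_R, K_I = K_I,
                 access_factors = access_factors,
                 perfusion_tau_s = perfusion_tau_s,
                 inactivated_states = inactivated_states,
                 bound_conducting = bound_conducting,
                 name = name),
            class = "compound_mechanism")
}

rate_at <- function(A, k_V, V) if (is.infinite(k_V)) A else A * exp(V / k_V)

state_K <- function(channel, drug) {
  ifelse(channel$states %in% drug$inactivated_states, drug$K_I, drug$K_R)
}

state_access <- function(channel, drug) {
  af <- rep(1, length(channel$states))
  names(af) <- channel$states
  if (!is.null(drug$access_factors)) {
    unknown <- setdiff(names(drug$access_factors), channel$states)
    if (length(unknown)) stop("access factor for unknown state: ",
                              paste(unknown, collapse = ", "))
    af[names(drug$access_factors)] <- drug$access_factors
  }
  af
}

#' Generator matrix of the channel-drug Markov process
#'
#' Builds the infinitesimal generator over the doubled state space
#' \{gating states\} x \{unbound, bound\} at a fixed membrane potential and
#' drug concentration. Binding to state \code{s} proceeds at
#' \code{access[s] * k_on * conc}; unbinding at \code{k_on * K} with the
#' class-specific dissociation constant. Gating rates among bound states are
#' rescaled so that every unbound-bound four-state cycle satisfies
#' microscopic reversibility; by convention the rescaling is absorbed by the
#' rate leading away from the higher-affinity side of each transition, so
#' the bound inactivation backward rate carries the full K_R/K_I factor
#' (bound channels recover slowly -- the kinetic basis of use-dependent
#' block).
#'
#' @param channel a [channel_model()].
#' @param drug a [compound_mechanism()].
#' @param V membrane potential, mV.
#' @param conc drug concentration, uM (>= 0).
#' @return square generator matrix with rows summing to zero; bound states
#'   are suffixed \code{":B"}.
#' @export
build_rate_matrix <- function(channel, drug, V, conc) {
  stopifnot(inherits(channel, "channel_model"),
            inherits(drug, "compound_mechanism"))
  if (!is.numeric(conc) || length(conc) != 1L || conc < 0)
    stop("concentration must be a single non-negative number")
  n <- length(channel$states)
  nm <- c(channel$states, paste0(channel$states, ":B"))
  Q <- matrix(0, 2 * n, 2 * n, dimnames = list(nm, nm))
  Ks <- state_K(channel, drug)
  af <- state_access(channel, drug)
  tr <- channel$transitions

  # unbound gating block
  for (i in seq_len(nrow(tr)))
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] +
      rate_at(tr$A[i], tr$k_V[i], V)

  # bound gating block: rescaled for cycle closure. Each undirected edge is
  # handled once using its forward/backward pair.
  edges <- unique(t(apply(tr[, c("from", "to")], 1, sort)))
  for (e in seq_len(nrow(edges))) {
    s1 <- edges[e, 1]; s2 <- edges[e, 2]
    f <- Q[s1, s2]; b <- Q[s2, s1]
    K1 <- Ks[match(s1, channel$states)]; K2 <- Ks[match(s2, channel$states)]
    a1 <- af[s1]; a2 <- af[s2]
    if (isTRUE(all.equal(K1 * a2, K2 * a1))) {
      gf <- f; gb <- b
    } else if ((f == 0) != (b == 0)) {
      stop("cycle closure impossible: one-way gating transition ",
           s1, "<->", s2, " links states with different bound affinity")
    } else if (K2 * a1 < K1 * a2) {
      # s2 side is higher affinity: keep the rate toward it, scale the return
      gf <- f
      gb <- b * (a1 * K2) / (a2 * K1)
    } else {
      gf <- f * (a2 * K1) / (a1 * K2)
      gb <- b
    }
    Q[paste0(s1, ":B"), paste0(s2, ":B")] <- gf
    Q[paste0(s2, ":B"), paste0(s1, ":B")] <- gb
  }

  # binding / unbinding
  for (i in seq_len(n)) {
    s <- channel$states[i]
    Q[s, paste0(s, ":B")] <- af[s] * drug$k_on * conc
    Q[paste0(s, ":B"), s] <- drug$k_on * Ks[i]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Eigendecomposition cache entry for fast repeated propagation under a
# fixed generator. p(t) = p0 %*% expm(Q t) = Re((p0 V) diag(e^{lambda t}) V^-1)
qdecomp <- function(Q) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  ok <- FALSE
  if (!is.null(e)) {
    vinv <- tryCatch(solve(e$vectors), error = function(err) NULL)
    if (!is.null(vinv)) {
      # sanity: reconstruction error of Q
      err <- max(Mod(e$vectors %*% diag(e$values, nrow(Q)) %*% vinv - Q))
      ok <- is.finite(err) && err < 1e-8 * max(1, max(abs(Q)))
    }
  }
  if (ok) list(ok = TRUE, V = e$vectors, Vinv = vinv, lambda = e$values, Q = Q)
  else list(ok = FALSE, Q = Q)
}

# occupancy rows at the requested times (matrix len(times) x n)
occupancy_path <- function(p0, dec, times) {
  if (dec$ok) {
    W <- as.vector(p0 %*% dec$V)
    E <- exp(outer(times, dec$lambda))
    P <- Re(E %*% (W * dec$Vinv))
  } else {
    # fall back to stepwise matrix exponentials (defective generator)
    P <- matrix(NA_real_, length(times), length(p0))
    for (i in seq_along(times))
      P[i, ] <- as.vector(p0 %*% as.matrix(Matrix::expm(dec$Q * times[i])))
  }
  P[P < 0 & P > -1e-9] <- 0
  P / rowSums(P)
}

#' Propagate a state-occupancy vector under a constant generator
#'
#' Solves the master equation \code{dp/dt = p Q} for a holding time at
#' constant voltage and concentration, via the eigendecomposition of
#' \code{Q} (with a matrix-exponential fallback for defective generators).
#'
#' @param occupancy probability vector over the generator's states
#'   (non-negative, summing to 1 within 1e-6).
#' @param Q generator matrix from [build_rate_matrix()].
#' @param duration_ms holding time, ms (>= 0).
#' @return occupancy vector after \code{duration_ms}; entries are
#'   non-negative and sum to 1 within 1e-9.
#' @export
propagate <- function(occupancy, Q, duration_ms) {
  if (!is.numeric(occupancy) || length(occupancy) != nrow(Q) ||
      any(occupancy < -1e-12) || abs(sum(occupancy) - 1) > 1e-6)
    stop("occupancy must be a probability vector over the generator's states")
  stopifnot(duration_ms >= 0)
  if (duration_ms == 0) return(occupancy)
  p <- occupancy_path(occupancy, qdecomp(Q), duration_ms)[1, ]
  names(p) <- rownames(Q)
  p
}

#' Stationary occupancy of a generator
#'
#' @param Q generator matrix.
#' @return the equilibrium probability vector (left null vector of Q).
#' @export
equilibrium_occupancy <- function(Q) {
  n <- nrow(Q)
  p <- as.vector(qr.solve(rbind(t(Q), rep(1, n)), c(rep(0, n), 1)))
  p[p < 0 & p > -1e-12] <- 0
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}
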