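# Compound mechanism presets and literature reference values -------------

#' Mechanism presets for simulation studies
#'
#' Qualitative kinetic templates spanning the mechanistic space covered by
#' well-known sodium-channel inhibitors. Affinities are round numbers near
#' published estimates; the association rate sets the micro-kinetics via
#' the inactivated-state unbinding time constant \code{1/(k_on * K_I)},
#' which (with bound-state gating recovery slowed by the affinity ratio)
#' governs how fast potency decays during hyperpolarizing gaps:
#' \describe{
#'   \item{riluzole_like}{strong state dependence (K_R/K_I = 100), fast
#'     micro-offset (~3 ms), slow perfusion offset.}
#'   \item{lidocaine_like}{moderate state dependence, intermediate
#'     micro-kinetics (offset tens of ms).}
#'   \item{benzocaine_like}{very fast micro-kinetics (offset < 1 ms): most
#'     of the bound fraction escapes detection after any hyperpolarizing
#'     gap.}
#'   \item{bupivacaine_like}{slow micro-kinetics (offset hundreds of ms),
#'     shallow apparent state dependence.}
#'   \item{ttx_like}{nearly state-independent pore blocker with fast
#'     binding, the flat-EIP reference.}
#' }
#'
#' @param name preset name.
#' @return a [compound_mechanism()].
#' @export
mechanism_preset <- function(name = c("riluzole_like", "lidocaine_like",
                                      "benzocaine_like", "bupivacaine_like",
                                      "ttx_like")) {
  name <- match.arg(name)
  switch(name,
    riluzole_like = compound_mechanism(
      k_on = 1 / 30, K_R = 1000, K_I = 10,
      perfusion_tau_s = 13.6, name = name),
    lidocaine_like = compound_mechanism(
      k_on = 1.1e-3, K_R = 1200, K_I = 18,
      perfusion_tau_s = 1.7, name = name),
    benzocaine_like = compound_mechanism(
      k_on = 0.025, K_R = 2200, K_I = 80,
      perfusion_tau_s = 1.4, name = name),
    bupivacaine_like = compound_mechanism(
      k_on = 2.6e-4, K_R = 95, K_I = 13,
      perfusion_tau_s = 3.6, name = name),
    ttx_like = compound_mechanism(
      k_on = 100, K_R = 0.028, K_I = 0.017,
      perfusion_tau_s = 3, name = name)
  )
}

#' Published reference estimates for five sodium-channel inhibitors
#'
#' Literature affinity and kinetics estimates for riluzole, lidocaine,
#' benzocaine, bupivacaine and tetrodotoxin on NaV1.4 channels, used as
#' realism anchors in worked examples and consistency checks: resting- and
#' inactivated-state dissociation constants (uM), their ratio, the
#' macroscopic washout time constant (s) and the micro-onset/offset time
#' ranges (ms).
#'
#' @return data frame with one row per compound.
#' @export
reference_affinities <- function() {
  data.frame(
    compound = c("riluzole", "lidocaine", "benzocaine", "bupivacaine",
                 "tetrodotoxin"),
    K_R_uM = c(1362, 1283, 2245, 94.6, 0.028),
    K_I_uM = c(5.63, 18.4, 79.4, 12.7, 0.017),
    K_ratio = c(242, 69.7, 28.3, 7.48, 1.7),
    macro_offset_tau_s = c(13.6, 1.72, 1.42, 3.56, 22.9),
    micro_onset_lo_ms = c(1, 1, 0.1, 100, 1),
    micro_onset_hi_ms = c(10, 100, 2, 1000, 100),
    micro_offset_lo_ms = c(2, 10, 0.1, 100, 1),
    micro_offset_hi_ms = c(10, 500, 4, 1000, 10),
    stringsAsFactors = FALSE
  )
}

#' Typical experiment concentration sets per preset
#'
#' Three or four log-spaced concentrations bracketing each preset's
#' apparent affinity at a depolarized holding potential, mirroring common
#' experimental designs for these compound classes.
#'
#' @param name preset name as in [mechanism_preset()].
#' @return numeric vector of concentrations, uM.
#' @export
preset_concentrations <- function(name = c("riluzole_like", "lidocaine_like",
                                           "benzocaine_like",
                                           "bupivacaine_like", "ttx_like")) {
  name <- match.arg(name)
  switch(name,
    riluzole_like = c(10, 30, 100, 300),
    lidocaine_like = c(100, 300, 1000),
    benzocaine_like = c(100, 300, 1000),
    bupivacaine_like = c(10, 30, 100),
    ttx_like = c(0.01, 0.03, 0.1)
  )
}
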