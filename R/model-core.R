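#' State vector of the homogeneous fast EEG system
#'
#' The fast system has 14 components, in fixed order: the mean soma membrane
#' potentials `h_e`, `h_i` (mV); the synaptic responses `I_lk` (mV) and their
#' auxiliary first-order companions `J_lk` (mV/ms) for the four connection
#' classes ee, ei, ie, ii; and the cortico-cortical pulse densities `phi_ek`
#' (per ms) with auxiliaries `psi_ek` (per ms^2) for the two excitatory
#' long-range projections.
#'
#' @param h membrane potentials `c(e=, i=)` (mV).
#' @param I synaptic responses, named by synapse label (mV).
#' @param J auxiliary synaptic states (mV/ms).
#' @param phi cortico-cortical pulse densities `c(ee=, ei=)` (per ms).
#' @param psi telegraph auxiliaries `c(ee=, ei=)` (per ms^2).
#' @return A named numeric vector of length 14 with class `meso_state`.
#' @export
fast_state <- function(h = c(e = 0, i = 0),
                       I = c(ee = 0, ei = 0, ie = 0, ii = 0),
                       J = c(ee = 0, ei = 0, ie = 0, ii = 0),
                       phi = c(ee = 0, ei = 0),
                       psi = c(ee = 0, ei = 0)) {
  y <- c(h_e = unname(h["e"]), h_i = unname(h["i"]),
         stats::setNames(unname(I[SYN]), paste0("I_", SYN)),
         stats::setNames(unname(J[SYN]), paste0("J_", SYN)),
         stats::setNames(unname(phi[c("ee", "ei")]), paste0("phi_", c("ee", "ei"))),
         stats::setNames(unname(psi[c("ee", "ei")]), paste0("psi_", c("ee", "ei"))))
  if (length(y) != 14L || any(!is.finite(y))) stop("invalid fast state")
  structure(y, class = "meso_state")
}

state_names <- function() {
  c("h_e", "h_i", paste0("I_", SYN), paste0("J_", SYN),
    paste0("phi_", c("ee", "ei")), paste0("psi_", c("ee", "ei")))
}

as_fast_state <- function(y) {
  y <- as.numeric(y)
  if (length(y) != 14L) stop("fast state must have 14 components")
  if (any(!is.finite(y))) stop("non-finite fast state")
  structure(stats::setNames(y, state_names()), class = "meso_state")
}

#' Mean population firing rate
#'
#' The instantaneous sigmoid firing function
#' `S_k(h) = S_max_k / (1 + exp(-c (h - mu_bar_k) / sigma_k))`, with slope
#' constant `c = P$sigmoid_slope` (default `sqrt(2)`).  Strictly increasing
#' in `h`, bounded in `(0, S_max_k)`, and equal to `S_max_k / 2` at the mean
#' threshold `mu_bar_k`.
#'
#' @param h membrane potential(s), mV (vectorized).
#' @param pop population label, `"e"` or `"i"`.
#' @param P a [model_parameters()] object.
#' @return Firing rate(s), per ms.
#' @export
firing_rate <- function(h, pop, P) {
  pop <- match.arg(pop, POP)
  if (any(!is.finite(h))) stop("non-finite membrane potential")
  P$S_max[[pop]] /
    (1 + exp(-P$sigmoid_slope * (h - P$mu_bar[[pop]]) / P$sigma[[pop]]))
}

#' Rate pair of the extended PSP kinetics
#'
#' The extended postsynaptic-potential operator factorizes into two
#' first-order stages with rates `gamma = eps * gamma0 / (e^eps - 1)` and
#' `gamma_tilde = gamma * e^eps`.  As `eps -> 0` both converge to `gamma0`
#' (critically damped limit); the `eps = 0` case is handled analytically.
#' The time to peak of the impulse response is `1/gamma0` for every `eps`.
#'
#' @param eps decay-shape factor, >= 0.
#' @param gamma0 reciprocal time-to-peak, per ms, > 0.
#' @return Named numeric `c(gamma=, gamma_tilde=)`, per ms.
#' @export
gamma_pair <- function(eps, gamma0) {
  if (!is.finite(eps) || eps < 0) stop("eps must be finite and >= 0")
  if (!is.finite(gamma0) || gamma0 <= 0) stop("gamma0 must be > 0")
  if (eps == 0) return(c(gamma = gamma0, gamma_tilde = gamma0))
  g <- eps * gamma0 / expm1(eps)
  c(gamma = g, gamma_tilde = g * exp(eps))
}

#' Unitary postsynaptic potential
#'
#' Impulse response of the synaptic operator: for `eps = 0` the classical
#' alpha function `Gamma * gamma0 * t * exp(1 - gamma0 * t)`; for `eps > 0`
#' the biexponential response of the two-stage cascade with rates from
#' [gamma_pair()] and drive normalization
#' `gamma_tilde * exp(gamma/gamma0) * Gamma`, which preserves the peak
#' amplitude `Gamma` at `t = 1/gamma0` while prolonging the decay tail as
#' `eps` grows.  Zero for `t < 0`.
#'
#' @param t time since the presynaptic impulse, ms (vectorized).
#' @param Gamma peak amplitude, mV (> 0).
#' @param gamma0 reciprocal time-to-peak, per ms.
#' @param eps decay-shape factor, >= 0.
#' @return PSP amplitude(s), mV.
#' @export
unitary_psp <- function(t, Gamma, gamma0, eps = 0) {
  if (!is.finite(Gamma) || Gamma <= 0) stop("Gamma must be > 0")
  gp <- gamma_pair(eps, gamma0)  # validates eps, gamma0
  out <- numeric(length(t))
  pos <- t >= 0 & is.finite(t)
  tp <- t[pos]
  if (eps < 1e-12) {
    out[pos] <- Gamma * gamma0 * tp * exp(1 - gamma0 * tp)
  } else {
    g <- gp[["gamma"]]; gt <- gp[["gamma_tilde"]]
    # (exp(-g t) - exp(-gt t)) / (gt - g), written via expm1 so that the
    # near-critically-damped regime (tiny eps) does not cancel
    delta <- gt - g  # equals eps * gamma0 exactly
    core <- exp(-g * tp) * (-expm1(-delta * tp)) / delta
    out[pos] <- gt * exp(g / gamma0) * Gamma * core
  }
  out
}

#' Presynaptic drive per connection class
#'
#' Total rate of incoming axonal pulses for each connection: local
#' intracortical input `N_beta_lk * S_l(h_l)`, plus long-range
#' cortico-cortical flux `phi_ek` (excitatory sources only), plus the tonic
#' extra-cortical rate `p_lk`.
#'
#' @param state a 14-component fast state (see [fast_state()]).
#' @param P a [model_parameters()] object.
#' @param p_override optional named replacement of the tonic rates, e.g.
#'   `c(p_ee = 4)`; unnamed entries are an error.
#' @return Named numeric `A` with one entry per synapse label, per ms.
#' @export
synaptic_drive <- function(state, P, p_override = NULL) {
  y <- as_fast_state(state)
  p <- P$p
  if (!is.null(p_override)) {
    nm <- sub("^p_", "", names(p_override))
    if (is.null(names(p_override)) || !all(nm %in% SYN))
      stop("p_override must be named by p-symbol (p_ee, p_ei, p_ie, p_ii)")
    p[nm] <- as.numeric(p_override)
  }
  Se <- firing_rate(y[["h_e"]], "e", P)
  Si <- firing_rate(y[["h_i"]], "i", P)
  c(ee = P$N_beta[["ee"]] * Se + y[["phi_ee"]] + p[["ee"]],
    ei = P$N_beta[["ei"]] * Se + y[["phi_ei"]] + p[["ei"]],
    ie = P$N_beta[["ie"]] * Si + p[["ie"]],
    ii = P$N_beta[["ii"]] * Si + p[["ii"]])
}

# ionic weighting of synaptic input: +1 at rest for excitatory reversal
# potentials, -1 for inhibitory ones, linear in h, vanishing at the
# reversal potential
ionic_weight <- function(h, lk, P) {
  k <- substr(lk, 2, 2)
  (P$h_eq[[lk]] - h) / abs(P$h_eq[[lk]] - P$h_rest[[k]])
}

#' Right-hand side of the fast EEG system
#'
#' Time derivatives of the 14 fast state components: membrane equations with
#' ionic weighting of the synaptic responses, the two-stage PSP kinetics
#' (reducing to the critically damped form at `eps = 0`), and the
#' spatially homogeneous telegraph dynamics of the cortico-cortical flux.
#' This is the reference R implementation; the compiled integrator evaluates
#' an identical right-hand side.
#'
#' @inheritParams synaptic_drive
#' @param Gamma_dyn optional named replacement of selected synaptic peak
#'   amplitudes (mV), e.g. `c(ii = 1.2)` - the hook through which the slow
#'   modulatory systems act.
#' @return Named numeric vector of 14 time derivatives.
#' @export
fast_rhs <- function(state, P, p_override = NULL, Gamma_dyn = NULL) {
  y <- as_fast_state(state)
  A <- synaptic_drive(y, P, p_override)
  G <- P$Gamma
  if (!is.null(Gamma_dyn)) {
    if (is.null(names(Gamma_dyn)) || !all(names(Gamma_dyn) %in% SYN))
      stop("Gamma_dyn must be named by synapse label")
    G[names(Gamma_dyn)] <- as.numeric(Gamma_dyn)
  }
  dI <- dJ <- stats::setNames(numeric(4), SYN)
  for (lk in SYN) {
    gp <- gamma_pair(P$eps[[lk]], P$gamma0[[lk]])
    drive <- gp[["gamma_tilde"]] * exp(gp[["gamma"]] / P$gamma0[[lk]]) *
      G[[lk]] * A[[lk]]
    dI[lk] <- y[[paste0("J_", lk)]] - gp[["gamma_tilde"]] * y[[paste0("I_", lk)]]
    dJ[lk] <- drive - gp[["gamma"]] * y[[paste0("J_", lk)]]
  }
  he <- y[["h_e"]]; hi <- y[["h_i"]]
  dhe <- (P$h_rest[["e"]] - he + ionic_weight(he, "ee", P) * y[["I_ee"]] +
            ionic_weight(he, "ie", P) * y[["I_ie"]]) / P$tau[["e"]]
  dhi <- (P$h_rest[["i"]] - hi + ionic_weight(hi, "ei", P) * y[["I_ei"]] +
            ionic_weight(hi, "ii", P) * y[["I_ii"]]) / P$tau[["i"]]
  Se <- firing_rate(he, "e", P)
  a <- P$v * P$Lambda
  dphi <- stats::setNames(
    y[c("psi_ee", "psi_ei")] - a * y[c("phi_ee", "phi_ei")], c("ee", "ei"))
  dpsi <- stats::setNames(
    a^2 * P$N_alpha * Se - a * y[c("psi_ee", "psi_ei")], c("ee", "ei"))
  stats::setNames(c(dhe, dhi, dI, dJ, dphi, dpsi), state_names())
}

# --- engine parameter vector ------------------------------------------------

# Flat 58-slot double vector consumed by the compiled right-hand side; layout
# mirrors the enum in src/integrator.cpp.  `slow` is a meso_slow config (or
# NULL for the pure fast system).
param_engine_vector <- function(P, slow = NULL) {
  pv <- c(P$h_rest, P$tau, P$h_eq, P$Gamma, P$gamma0, P$eps,
          P$N_alpha, P$N_beta, P$v, P$Lambda,
          P$S_max, P$mu_bar, P$sigma, P$p, P$sigmoid_slope)
  slow_block <- numeric(17)  # law, n_slow, slot map(4), mu(2), ab(4), G0(4), floor
  if (!is.null(slow)) {
    stopifnot(inherits(slow, "meso_slow"))
    slow_block[1] <- if (slow$law == "SS1") 1 else 2
    slow_block[2] <- length(slow$targets)
    slot <- match(SYN, slow$targets)
    slot[is.na(slot)] <- 0
    slow_block[3:6] <- slot
    slow_block[7:8] <- slow$mu[POP]
    if (slow$law == "SS1") {
      slow_block[9:12] <- c(slow$theta[POP], slow$k[POP])
    } else {
      slow_block[9:12] <- c(slow$kappa[POP], slow$xi[POP])
      slow_block[13:16] <- slow$Gamma0[SYN]
    }
    slow_block[17] <- as.numeric(isTRUE(slow$floor))
  }
  unname(c(pv, slow_block))
}
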