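#' Configure a slow synaptic-depression system
#'
#' The slow modulatory system evolves the peak amplitudes `Gamma_lk` of a
#' chosen set of synaptic connection classes on a timescale `1/mu` much
#' longer than the fast EEG dynamics, emulating activity-dependent
#' short-term synaptic depression.  Two laws are available:
#'
#' * **SS1** (linear recovery/depletion):
#'   `dGamma_lk/dt = mu_l * (theta_l - k_l * S_l(h_l))`, with independently
#'   specifiable recovery rate `mu_l * theta_l` and depletion gain
#'   `mu_l * k_l`.  Amplitudes are unbounded by principle; an optional floor
#'   at 0 mV can be enabled (`floor = TRUE`, default off).
#' * **SS2** (bounded sigmoidal depression):
#'   `dGamma_lk/dt = mu_l * (Gamma0_lk / (1 + exp(kappa_l (h_l - xi_l))) - Gamma_lk)`,
#'   keeping each amplitude in `(0, Gamma0_lk]` and decreasing monotonically
#'   with the source population's depolarization past the threshold `xi_l`.
#'
#' All parameters are per source population `l` in `{e, i}`; every modulated
#' connection inherits the law of its source.  Internal units: `mu` per ms,
#' `theta` mV, `k` mV*ms (mV per unit per-ms firing rate), `kappa` per mV,
#' `xi` mV.
#'
#' @param law `"SS1"` or `"SS2"`.
#' @param targets character vector of modulated synapse labels (subset of
#'   `ee`, `ei`, `ie`, `ii`), nonempty.
#' @param mu inverse slow timescales `c(e=, i=)`, per ms.  Entries for
#'   sources with no modulated target are ignored.
#' @param theta SS1 recovery levels `c(e=, i=)`, mV.
#' @param k SS1 depletion gains `c(e=, i=)`, mV*ms.
#' @param kappa SS2 threshold sensitivities `c(e=, i=)`, per mV.
#' @param xi SS2 depression thresholds `c(e=, i=)`, mV; `NULL` (default for
#'   SS2) anchors each threshold at the fixed-point membrane potential of
#'   the unmodulated fast system at simulation time.
#' @param Gamma0 SS2 resting amplitudes, named by synapse label; defaults to
#'   the model's `Gamma` at simulation time.
#' @param Gamma_init initial amplitudes, named by target label; defaults to
#'   the model's `Gamma`.
#' @param floor SS1 only: clamp amplitudes at 0 mV (default `FALSE`).
#' @return An object of class `meso_slow`.
#' @seealso [preset_slow()], [coupled_rhs()], [simulate_model()]
#' @export
slow_config <- function(law = c("SS1", "SS2"), targets,
                        mu = c(e = 0.001, i = 0.001),
                        theta = c(e = 0, i = 0), k = c(e = 0, i = 0),
                        kappa = c(e = 0, i = 0), xi = NULL,
                        Gamma0 = NULL, Gamma_init = NULL, floor = FALSE) {
  law <- match.arg(law)
  targets <- as.character(targets)
  if (length(targets) == 0L || !all(targets %in% SYN) || anyDuplicated(targets))
    stop("targets must be a nonempty set of distinct synapse labels")
  full2 <- function(x, default = 0) {
    out <- c(e = default, i = default)
    if (!is.null(x)) out[names(x)] <- as.numeric(x)
    out
  }
  cfg <- structure(list(
    law = law, targets = targets,
    mu = full2(mu), theta = full2(theta), k = full2(k),
    kappa = full2(kappa),
    xi = if (is.null(xi)) NULL else full2(xi),
    Gamma0 = if (is.null(Gamma0)) NULL else Gamma0,
    Gamma_init = Gamma_init,
    floor = isTRUE(floor)
  ), class = "meso_slow")
  used <- unique(substr(targets, 1, 1))
  if (any(cfg$mu[used] < 0)) stop("mu must be >= 0")
  if (law == "SS1" && any(cfg$k[used] < 0)) stop("SS1 depletion gain k must be >= 0")
  if (law == "SS2" && any(cfg$kappa[used] <= 0)) stop("SS2 kappa must be > 0")
  cfg
}

#' @export
print.meso_slow <- function(x, ...) {
  cat("<meso_slow>", x$law, "modulating", paste(x$targets, collapse = ", "), "\n")
  cat(sprintf("  mu (per ms): e=%g i=%g\n", x$mu["e"], x$mu["i"]))
  if (x$law == "SS1") {
    cat(sprintf("  theta (mV): e=%g i=%g   k (mV ms): e=%g i=%g   floor=%s\n",
                x$theta["e"], x$theta["i"], x$k["e"], x$k["i"], x$floor))
  } else {
    xi <- if (is.null(x$xi)) "fixed point (anchored at run time)"
          else sprintf("e=%g i=%g", x$xi["e"], x$xi["i"])
    cat(sprintf("  kappa (per mV): e=%g i=%g   xi (mV): %s\n",
                x$kappa["e"], x$kappa["i"], xi))
  }
  invisible(x)
}

#' Resolve a slow configuration's run-time defaults against a model
#'
#' Fills in the defaults that depend on the fast system: SS2 thresholds
#' `xi` are anchored at the membrane potentials of the unmodulated fast
#' system's fixed point, resting amplitudes `Gamma0` and initial amplitudes
#' default to the model's `Gamma`.  [simulate_model()] and [coupled_rhs()]
#' call this automatically; call it explicitly to freeze the anchoring
#' before sweeping model parameters (so the thresholds do not move with the
#' swept fixed point).
#'
#' @param slow a [slow_config()] or `NULL`.
#' @param P a [model_parameters()] object.
#' @return The resolved `meso_slow` (or `NULL`).
#' @export
resolve_slow <- function(slow, P) {
  if (!is.null(slow) && inherits(slow, "meso_slow") &&
      isTRUE(attr(slow, "resolved"))) return(slow)
  if (is.null(slow)) return(NULL)
  stopifnot(inherits(slow, "meso_slow"))
  if (slow$law == "SS2") {
    if (is.null(slow$xi)) {
      fp <- find_fixed_point(P)
      slow$xi <- c(e = unname(fp$state[["h_e"]]), i = unname(fp$state[["h_i"]]))
    }
    g0 <- P$Gamma
    if (!is.null(slow$Gamma0)) g0[names(slow$Gamma0)] <- as.numeric(slow$Gamma0)
    slow$Gamma0 <- g0
  } else {
    slow$Gamma0 <- P$Gamma
  }
  gi <- P$Gamma[slow$targets]
  if (!is.null(slow$Gamma_init)) gi[names(slow$Gamma_init)] <- as.numeric(slow$Gamma_init)
  slow$Gamma_init <- stats::setNames(unname(gi[slow$targets]), slow$targets)
  tmscale <- max(slow$mu[unique(substr(slow$targets, 1, 1))])
  if (tmscale >= 0.01)
    warning("slow timescale mu = ", tmscale,
            " per ms is not well separated from the fast dynamics ",
            "(expect mu * tau << 1)", call. = FALSE)
  attr(slow, "resolved") <- TRUE
  slow
}

#' Slow-system derivative, SS1 law
#'
#' `dGamma_lk/dt = mu_l * (theta_l - k_l * S_l(h_l))` for every modulated
#' connection; connections sharing a source population share a derivative.
#'
#' @param slow_state named numeric of current amplitudes, one entry per
#'   modulated synapse label (mV).
#' @param h membrane potentials `c(e=, i=)` (mV).
#' @param slow a `meso_slow` configuration with `law = "SS1"`.
#' @param P a [model_parameters()] object (for the firing sigmoid).
#' @return Named numeric of amplitude derivatives, mV per ms.
#' @export
ss1_rhs <- function(slow_state, h, slow, P) {
  stopifnot(slow$law == "SS1")
  check_slow_state(slow_state, slow)
  out <- vapply(names(slow_state), function(lk) {
    l <- substr(lk, 1, 1)
    d <- slow$mu[[l]] * (slow$theta[[l]] - slow$k[[l]] * firing_rate(h[[l]], l, P))
    if (slow$floor && slow_state[[lk]] <= 0 && d < 0) d <- 0
    d
  }, numeric(1))
  out
}

#' Slow-system derivative, SS2 law
#'
#' `dGamma_lk/dt = mu_l * (Gamma0_lk / (1 + exp(kappa_l (h_l - xi_l))) - Gamma_lk)`.
#' At fixed `h` each amplitude relaxes exponentially, at rate `mu_l`, to the
#' bounded equilibrium `Gamma0_lk / (1 + exp(kappa_l (h_l - xi_l)))`, which
#' decreases monotonically with source depolarization.
#'
#' @inheritParams ss1_rhs
#' @param slow a `meso_slow` configuration with `law = "SS2"` whose run-time
#'   defaults have been resolved (`xi` and `Gamma0` set; see [slow_config()]).
#' @return Named numeric of amplitude derivatives, mV per ms.
#' @export
ss2_rhs <- function(slow_state, h, slow) {
  stopifnot(slow$law == "SS2")
  if (is.null(slow$xi) || is.null(slow$Gamma0))
    stop("SS2 configuration has unresolved xi/Gamma0; pass it through a ",
         "model first (simulate_model/coupled_rhs resolve defaults)")
  check_slow_state(slow_state, slow)
  out <- vapply(names(slow_state), function(lk) {
    l <- substr(lk, 1, 1)
    target <- slow$Gamma0[[lk]] / (1 + exp(slow$kappa[[l]] * (h[[l]] - slow$xi[[l]])))
    slow$mu[[l]] * (target - slow_state[[lk]])
  }, numeric(1))
  out
}

check_slow_state <- function(slow_state, slow) {
  if (is.null(names(slow_state)) || !setequal(names(slow_state), slow$targets))
    stop("slow state labels (", paste(names(slow_state), collapse = ","),
         ") do not match the configured targets (",
         paste(slow$targets, collapse = ","), ")")
  if (any(!is.finite(slow_state))) stop("non-finite slow state")
  invisible(TRUE)
}

#' Coupled fast-slow right-hand side
#'
#' Evaluates the fast system with the modulated synaptic amplitudes replaced
#' by the current slow state, together with the slow derivatives of the
#' configured law.  With an empty slow configuration (`slow = NULL`) this is
#' identical to [fast_rhs()].
#'
#' @param state a 14-component fast state.
#' @param slow_state named amplitudes for every modulated synapse (mV), or
#'   `NULL` when `slow` is `NULL`.
#' @param P a [model_parameters()] object.
#' @param slow a `meso_slow` configuration, or `NULL`.
#' @param p_override optional tonic-rate replacement, as in [fast_rhs()].
#' @return List with components `fast` (14 derivatives) and `slow` (one per
#'   modulated amplitude, mV per ms; `NULL` if unmodulated).
#' @export
coupled_rhs <- function(state, slow_state = NULL, P, slow = NULL,
                        p_override = NULL) {
  if (is.null(slow)) {
    return(list(fast = fast_rhs(state, P, p_override), slow = NULL))
  }
  slow <- resolve_slow(slow, P)
  check_slow_state(slow_state, slow)
  h <- c(e = as_fast_state(state)[["h_e"]], i = as_fast_state(state)[["h_i"]])
  dslow <- if (slow$law == "SS1") ss1_rhs(slow_state, h, slow, P)
           else ss2_rhs(slow_state, h, slow)
  gd <- stats::setNames(as.numeric(slow_state), names(slow_state))
  list(fast = fast_rhs(state, P, p_override, Gamma_dyn = gd), slow = dslow)
}

#' Packaged slow-system configurations
#'
#' Reference bursting configurations:
#'
#' * `"fig3"`: SS1 acting on the inhibitory-inhibitory amplitude `Gamma_ii`
#'   only (`mu_i = 0.001` per ms, `theta_i = 0.1818` mV, `k_i = 10` mV*ms);
#'   the canonical recurrent-bursting preset.
#' * `"fig3-alt"`: as `"fig3"` but modulating both inhibitory-source
#'   amplitudes `Gamma_ii` and `Gamma_ie`.
#' * `"fig6"`: SS1 on all four connection classes
#'   (`theta_e = 0.1818`, `k_e = 14`; `theta_i = 0.07`, `k_i = 10`).
#' * `"fig7"`: SS2 on all four classes (`kappa_e = 0.2`, `kappa_i = 0.1`
#'   per mV), thresholds anchored at the unmodulated fixed point; pair with
#'   `preset_model("fig7")`, whose prolonged inhibitory PSP decay
#'   (`eps_ii = 1.8`, `eps_ie = 1.5`) this configuration assumes.
#'
#' @param name preset name.
#' @return A `meso_slow` configuration.
#' @export
preset_slow <- function(name = c("fig3", "fig3-alt", "fig6", "fig7")) {
  name <- match.arg(name)
  switch(name,
    "fig3" = slow_config("SS1", targets = "ii",
                         mu = c(e = 0, i = 0.001),
                         theta = c(e = 0, i = 0.1818),
                         k = c(e = 0, i = 10)),
    "fig3-alt" = slow_config("SS1", targets = c("ie", "ii"),
                             mu = c(e = 0, i = 0.001),
                             theta = c(e = 0, i = 0.1818),
                             k = c(e = 0, i = 10)),
    "fig6" = slow_config("SS1", targets = SYN,
                         mu = c(e = 0.001, i = 0.001),
                         theta = c(e = 0.1818, i = 0.07),
                         k = c(e = 14, i = 10)),
    "fig7" = slow_config("SS2", targets = SYN,
                         mu = c(e = 0.001, i = 0.001),
                         kappa = c(e = 0.2, i = 0.1)))
}
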