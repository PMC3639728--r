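#' Population and synapse labels
#'
#' The model distinguishes two neuronal populations, excitatory (`"e"`) and
#' inhibitory (`"i"`), and the four synaptic connection classes between them,
#' labelled source-target: `"ee"`, `"ei"`, `"ie"`, `"ii"`.
#'
#' @return Character vectors of the valid labels.
#' @export
population_labels <- function() c("e", "i")

#' @rdname population_labels
#' @export
synapse_labels <- function() c("ee", "ei", "ie", "ii")

SYN <- c("ee", "ei", "ie", "ii")
POP <- c("e", "i")

#' Construct a model parameter set
#'
#' Bundles the full parameter vector of the spatially homogeneous fast EEG
#' system.  Internal units are millivolts, milliseconds and centimetres
#' throughout: rates and rate constants are per ms, conduction velocity is
#' cm/ms and the connectivity decay is per cm.  Defaults reproduce the
#' reference simulation set (see [preset_model()]).
#'
#' @param h_rest resting membrane potentials, named `c(e=, i=)` (mV).
#' @param tau passive membrane time constants per population (ms).
#' @param h_eq synaptic reversal potentials per connection
#'   `c(ee=, ei=, ie=, ii=)` (mV); the excitatory ones (`ee`, `ei`) must lie
#'   above and the inhibitory ones (`ie`, `ii`) below the target population's
#'   resting potential.
#' @param Gamma postsynaptic-potential peak amplitudes per connection (mV).
#' @param gamma0 reciprocal PSP time-to-peak per connection (per ms).
#' @param eps dimensionless PSP decay-shape factors (>= 0); 0 recovers the
#'   critically damped alpha-function kinetics, larger values prolong the
#'   decay of the PSP tail at fixed time-to-peak (the anesthetic axis).
#' @param N_alpha long-range (cortico-cortical) excitatory synapse counts on
#'   the two target populations, `c(ee=, ei=)`.
#' @param N_beta local (intracortical) synapse counts per connection.
#' @param v cortico-cortical axonal conduction velocity (cm/ms), per target.
#' @param Lambda decay rate of cortico-cortical connectivity strength with
#'   distance (per cm), per target.
#' @param S_max maximum population firing rates (per ms).
#' @param mu_bar mean firing thresholds (mV).
#' @param sigma firing-threshold spreads (mV).
#' @param p tonic extra-cortical input rates per connection (per ms); the
#'   inhibitory-source entries (`ie`, `ii`) default to 0 but are retained so
#'   tonic inhibition can be modelled.
#' @param sigmoid_slope slope constant of the firing sigmoid exponent
#'   (default `sqrt(2)`, matching the original model formulation).
#' @param check_ranges if `TRUE` (default), parameters outside the
#'   physiologically admissible ranges of [admissible_ranges()] raise a
#'   warning (never an error).
#'
#' @return An object of class `meso_params` (a named list of named numeric
#'   vectors).
#' @seealso [preset_model()], [admissible_ranges()], [read_parameters()]
#' @export
model_parameters <- function(h_rest = c(e = -68.1355, i = -77.2602),
                             tau    = c(e = 138.3660, i = 89.3207),
                             h_eq   = c(ee = -15.8527, ei = 7.4228,
                                        ie = -85.9896, ii = -84.5363),
                             Gamma  = c(ee = 0.3127, ei = 0.9426,
                                        ie = 0.4947, ii = 1.4122),
                             gamma0 = c(ee = 0.4393, ei = 0.2350,
                                        ie = 0.0791, ii = 0.0782),
                             eps    = c(ee = 0, ei = 0, ie = 0, ii = 0),
                             N_alpha = c(ee = 4994.4860, ei = 2222.9060),
                             N_beta  = c(ee = 4582.0661, ei = 4198.1829,
                                         ie = 989.5281, ii = 531.9419),
                             v      = c(ee = 0.1714, ei = 0.1714),
                             Lambda = c(ee = 0.2433, ei = 0.2433),
                             S_max  = c(e = 0.2801, i = 0.1228),
                             mu_bar = c(e = -47.1364, i = -45.3751),
                             sigma  = c(e = 2.6120, i = 2.8294),
                             p      = c(ee = 3.6032, ei = 0.3639,
                                        ie = 0, ii = 0),
                             sigmoid_slope = sqrt(2),
                             check_ranges = TRUE) {
  as_named <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, length(nm))
    stopifnot(length(x) == length(nm))
    stats::setNames(x, nm)
  }
  P <- structure(list(
    h_rest = as_named(h_rest, POP), tau = as_named(tau, POP),
    h_eq = as_named(h_eq, SYN), Gamma = as_named(Gamma, SYN),
    gamma0 = as_named(gamma0, SYN), eps = as_named(eps, SYN),
    N_alpha = as_named(N_alpha, c("ee", "ei")),
    N_beta = as_named(N_beta, SYN),
    v = as_named(v, c("ee", "ei")), Lambda = as_named(Lambda, c("ee", "ei")),
    S_max = as_named(S_max, POP), mu_bar = as_named(mu_bar, POP),
    sigma = as_named(sigma, POP), p = as_named(p, SYN),
    sigmoid_slope = as.numeric(sigmoid_slope)[1]
  ), class = "meso_params")
  validate_params(P, check_ranges = check_ranges)
  P
}

validate_params <- function(P, check_ranges = TRUE) {
  num <- unlist(P[setdiff(names(P), "sigmoid_slope")])
  if (any(!is.finite(num))) stop("non-finite model parameter")
  for (k in POP) {
    for (src in POP) {
      lk <- paste0(src, k)
      if (src == "e" && P$h_eq[lk] <= P$h_rest[k])
        stop("excitatory reversal potential h_eq_", lk,
             " must exceed the resting potential of population ", k)
      if (src == "i" && P$h_eq[lk] >= P$h_rest[k])
        stop("inhibitory reversal potential h_eq_", lk,
             " must lie below the resting potential of population ", k)
    }
  }
  pos <- c(P$tau, P$gamma0, P$S_max, P$sigma, P$v, P$Lambda)
  if (any(pos <= 0)) stop("tau, gamma0, S_max, sigma, v, Lambda must be > 0")
  if (any(P$eps < 0)) stop("eps must be >= 0")
  if (any(P$p < 0)) stop("p must be >= 0")
  if (P$sigmoid_slope <= 0) stop("sigmoid_slope must be > 0")
  if (check_ranges) warn_out_of_range(P)
  invisible(P)
}

warn_out_of_range <- function(P) {
  rg <- admissible_ranges()
  bad <- character(0)
  for (sym in names(rg)) {
    v <- param_value(P, sym)
    if (v < rg[[sym]][1] || v > range_upper(rg, sym, P)) bad <- c(bad, sym)
  }
  if (length(bad))
    warning("parameter(s) outside the physiologically admissible ranges: ",
            paste(bad, collapse = ", "), call. = FALSE)
  invisible(bad)
}

#' @export
print.meso_params <- function(x, ...) {
  cat("<meso_params> spatially homogeneous fast EEG system\n")
  for (nm in setdiff(names(x), "sigmoid_slope")) {
    v <- x[[nm]]
    cat(sprintf("  %-8s %s\n", nm,
                paste(sprintf("%s=%g", names(v), v), collapse = "  ")))
  }
  cat(sprintf("  sigmoid slope constant: %g\n", x$sigmoid_slope))
  invisible(x)
}

# --- flat symbol access -----------------------------------------------------

param_symbols <- function() {
  c(paste0("h_rest_", POP), paste0("tau_", POP),
    paste0("h_eq_", SYN), paste0("Gamma_", SYN), paste0("gamma0_", SYN),
    paste0("eps_", SYN), paste0("N_alpha_", c("ee", "ei")),
    paste0("N_beta_", SYN), paste0("v_", c("ee", "ei")),
    paste0("Lambda_", c("ee", "ei")), paste0("S_max_", POP),
    paste0("mu_bar_", POP), paste0("sigma_", POP), paste0("p_", SYN))
}

split_symbol <- function(sym) {
  m <- regmatches(sym, regexec("^(.*)_(e|i|ee|ei|ie|ii)$", sym))[[1]]
  if (length(m) != 3L || !m[2] %in% c("h_rest", "tau", "h_eq", "Gamma",
                                      "gamma0", "eps", "N_alpha", "N_beta",
                                      "v", "Lambda", "S_max", "mu_bar",
                                      "sigma", "p"))
    stop("unknown model parameter symbol: ", sym)
  list(field = m[2], label = m[3])
}

#' Access a scalar model parameter by symbol
#'
#' Symbols follow the `field_label` convention, e.g. `"Gamma_ii"`,
#' `"gamma0_ee"`, `"p_ee"`, `"eps_ii"`, `"tau_e"`.
#'
#' @param P a `meso_params` object.
#' @param sym parameter symbol.
#' @param value replacement value.
#' @return `param_value` the scalar value; `set_param_value` a modified copy
#'   of `P` (not revalidated against admissible ranges).
#' @export
param_value <- function(P, sym) {
  s <- split_symbol(sym)
  unname(P[[s$field]][s$label])
}

#' @rdname param_value
#' @export
set_param_value <- function(P, sym, value) {
  s <- split_symbol(sym)
  P[[s$field]][s$label] <- as.numeric(value)
  P
}

# --- presets and file I/O ---------------------------------------------------

#' Reference model parameter sets
#'
#' `"table3"` is the normative reference set used throughout: a
#' physiologically admissible parameterization with a single stable fixed
#' point, low firing rates and an alpha-band fluctuation spectrum, from which
#' all bursting configurations are derived.  `"fig7"` is the same set with
#' prolonged inhibitory PSP decay (`eps_ii = 1.8`, `eps_ie = 1.5`), the fast
#' system used for the bounded (SS2) slow-modulation runs.
#'
#' @param name preset name.
#' @return A `meso_params` object.
#' @export
preset_model <- function(name = c("table3", "fig7")) {
  name <- match.arg(name)
  # the reference set's conduction velocity sits above the tabulated
  # admissible range; the preset is used as printed, so skip the range warning
  P <- model_parameters(check_ranges = FALSE)
  if (name == "fig7") {
    P$eps["ii"] <- 1.8
    P$eps["ie"] <- 1.5
  }
  P
}

#' Read or write a model parameter file
#'
#' Flat key-value YAML with one key per scalar parameter symbol (e.g.
#' `Gamma_ii`, `N_beta_ie`, `eps_ii`) plus `sigmoid_slope`.  Units are the
#' package-internal mV / ms / cm system.  The packaged file
#' `system.file("extdata", "table3.yaml", package = "mesoburst")` reproduces
#' the reference set exactly.
#'
#' @param path file path.
#' @param P a `meso_params` object.
#' @param check_ranges passed to [model_parameters()].
#' @return `read_parameters` a `meso_params`; `write_parameters` the path,
#'   invisibly.
#' @export
read_parameters <- function(path, check_ranges = TRUE) {
  kv <- yaml::read_yaml(path)
  P <- model_parameters(check_ranges = FALSE)
  for (sym in setdiff(names(kv), "sigmoid_slope")) {
    P <- set_param_value(P, sym, kv[[sym]])
  }
  if (!is.null(kv$sigmoid_slope)) P$sigmoid_slope <- as.numeric(kv$sigmoid_slope)
  validate_params(P, check_ranges = check_ranges)
  P
}

#' @rdname read_parameters
#' @export
write_parameters <- function(P, path) {
  stopifnot(inherits(P, "meso_params"))
  kv <- lapply(param_symbols(), function(sym) param_value(P, sym))
  names(kv) <- param_symbols()
  kv$sigmoid_slope <- P$sigmoid_slope
  writeLines(yaml::as.yaml(kv, precision = 17), path)
  invisible(path)
}

#' Physiologically admissible parameter ranges
#'
#' Lower and upper bounds per scalar parameter symbol, in internal units
#' (mV, ms, cm).  The upper bound of the inhibitory reversal potentials is
#' dependent: it must stay at least 5 mV below the target population's
#' resting potential and is therefore evaluated per candidate during
#' sampling and range checks.
#'
#' @return Named list of `c(lower, upper)` pairs; the dependent inhibitory
#'   reversal bounds carry the attribute `dependent = TRUE`.
#' @export
admissible_ranges <- function() {
  dep <- function(lo, hi) structure(c(lo, hi), dependent = TRUE)
  rg <- list()
  for (k in POP) {
    rg[[paste0("h_rest_", k)]] <- c(-80, -60)
    rg[[paste0("tau_", k)]] <- c(5, 150)
    rg[[paste0("S_max_", k)]] <- c(0.05, 0.5)
    rg[[paste0("mu_bar_", k)]] <- c(-55, -40)
    rg[[paste0("sigma_", k)]] <- c(2, 7)
  }
  for (lk in c("ee", "ei")) {
    rg[[paste0("h_eq_", lk)]] <- c(-20, 10)
    rg[[paste0("Gamma_", lk)]] <- c(0.1, 2.0)
    rg[[paste0("gamma0_", lk)]] <- c(1 / 10, 1 / 1)    # EPSP rise 1-10 ms
    rg[[paste0("N_alpha_", lk)]] <- c(1000, 5000)
    rg[[paste0("N_beta_", lk)]] <- c(2000, 5000)
    rg[[paste0("v_", lk)]] <- c(0.01, 0.1)             # 0.1-1 mm/ms in cm/ms
    rg[[paste0("Lambda_", lk)]] <- c(1 / 10, 1 / 1)    # decay scale 1-10 cm
  }
  for (lk in c("ie", "ii")) {
    rg[[paste0("h_eq_", lk)]] <- dep(-90, -65)  # true upper is h_rest_k - 5
    rg[[paste0("Gamma_", lk)]] <- c(0.1, 2.0)
    rg[[paste0("gamma0_", lk)]] <- c(1 / 100, 1 / 2)   # IPSP rise 2-100 ms
    rg[[paste0("N_beta_", lk)]] <- c(100, 1000)
  }
  for (lk in SYN) rg[[paste0("p_", lk)]] <- c(0, 10)
  rg
}

# upper bound for range checks; resolves the dependent inhibitory-reversal
# bound against the candidate's resting potential
range_upper <- function(rg, sym, P) {
  b <- rg[[sym]]
  if (isTRUE(attr(b, "dependent"))) {
    k <- substr(sym, nchar(sym), nchar(sym))
    return(P$h_rest[k] - 5)
  }
  b[2]
}
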