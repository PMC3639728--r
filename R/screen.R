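#' Sample candidate parameter sets from the admissible space
#'
#' Independent uniform draws per scalar parameter within the
#' physiologically admissible bounds (see [admissible_ranges()]); the
#' dependent upper bound of the inhibitory reversal potentials (at least
#' 5 mV below the target's resting potential) is enforced by rejection.
#' Reproducible under a seed.  The PSP decay-shape factors `eps` are held
#' at 0 (the admissible table predates the extended kinetics).
#'
#' @param n number of candidates.
#' @param seed integer seed (optional).
#' @param ranges bounds, as from [admissible_ranges()].
#' @return A list of `n` `meso_params` objects (range warnings suppressed:
#'   draws are within bounds by construction).
#' @export
sample_parameters <- function(n, seed = NULL, ranges = admissible_ranges()) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      P <- model_parameters(check_ranges = FALSE)
      for (sym in names(ranges)) {
        b <- ranges[[sym]]
        if (isTRUE(attr(b, "dependent"))) next  # drawn after h_rest below
        P <- set_param_value(P, sym, stats::runif(1, b[1], b[2]))
      }
      for (sym in names(ranges)) {
        b <- ranges[[sym]]
        if (!isTRUE(attr(b, "dependent"))) next
        upper <- range_upper(ranges, sym, P)
        repeat {
          v <- stats::runif(1, b[1], b[2])
          if (v <= upper) break
        }
        P <- set_param_value(P, sym, v)
      }
      validate_params(P, check_ranges = FALSE)
      P
    })
  })
}

#' Screen a parameter set against the normative resting-EEG criteria
#'
#' A candidate passes when (i) the fast system has a single located, stable
#' fixed point whose excitatory and inhibitory firing rates are below
#' `max_rate` (per s), and (ii) its linearized white-noise fluctuation
#' spectrum has a resonant peak within `alpha_band` and a negative log-log
#' slope over `slope_band` (the low-frequency "1/f" decay).  An optional
#' third screen emulates anesthetic loading by ramping the inhibitory PSP
#' decay-shape factor `eps_ii` and requires a transient increase of total
#' spectral power and a monotone decrease of mean frequency along the ramp.
#' Screening is deterministic.
#'
#' @param P a [model_parameters()] candidate.
#' @param drive drive channel for the spectrum.
#' @param freqs frequency grid, Hz.
#' @param alpha_band admissible peak-frequency window, Hz.
#' @param slope_band band for the low-frequency slope fit, Hz.
#' @param max_rate firing-rate ceiling, per s.
#' @param check_anesthetic also run the `eps_ii`-ramp screen.
#' @param eps_ramp ramp values used when `check_anesthetic = TRUE`.
#' @return An object of class `meso_verdict`: list with `passed`, the
#'   measured `alpha_peak_hz`, `low_freq_slope`, `rates_per_s`, `stable`,
#'   and `reasons` (character vector of failed criteria, empty on a pass).
#' @export
screen_normative <- function(P, drive = "p_ee",
                             freqs = seq(0.25, 60, by = 0.25),
                             alpha_band = c(8, 13), slope_band = c(1, 7),
                             max_rate = 20, check_anesthetic = FALSE,
                             eps_ramp = seq(0, 1.5, by = 0.25)) {
  reasons <- character(0)
  rates <- c(e = NA_real_, i = NA_real_)
  peak <- NA_real_; slope <- NA_real_; stable <- FALSE
  fp <- tryCatch(find_fixed_point(P), error = function(e) e)
  if (inherits(fp, "error")) {
    reasons <- c(reasons, paste("no fixed point:", conditionMessage(fp)))
  } else {
    stable <- fp$stable
    if (!stable) reasons <- c(reasons, "fixed point unstable")
    rates <- c(e = 1000 * firing_rate(fp$h[["e"]], "e", P),
               i = 1000 * firing_rate(fp$h[["i"]], "i", P))
    if (any(rates >= max_rate))
      reasons <- c(reasons, sprintf("firing rate %.1f per s >= %g per s",
                                    max(rates), max_rate))
    if (stable) {
      sp <- linear_spectrum(P, drive, freqs)
      peak <- attr(sp, "peak_frequency")
      slope <- attr(sp, "low_freq_slope")
      if (peak < alpha_band[1] || peak > alpha_band[2])
        reasons <- c(reasons, sprintf("spectral peak %.2f Hz outside [%g, %g]",
                                      peak, alpha_band[1], alpha_band[2]))
      if (!is.na(slope) && slope >= 0)
        reasons <- c(reasons, "no low-frequency spectral decay")
    }
  }
  anesthetic <- NULL
  if (check_anesthetic && length(reasons) == 0) {
    tot <- mf <- numeric(length(eps_ramp))
    for (i in seq_along(eps_ramp)) {
      Pi <- P
      Pi$eps["ii"] <- eps_ramp[i]
      sp <- tryCatch(linear_spectrum(Pi, drive, freqs),
                     error = function(e) NULL)
      if (is.null(sp)) { tot[i] <- NA; mf[i] <- NA; next }
      tot[i] <- sum(sp$power)
      mf[i] <- sum(sp$frequency * sp$power) / sum(sp$power)
    }
    ok <- !is.na(tot)
    power_up <- any(tot[ok][-1] > tot[ok][1])
    freq_down <- all(diff(mf[ok]) <= 1e-9)
    anesthetic <- list(eps = eps_ramp, total_power = tot, mean_freq = mf,
                       power_transient_increase = power_up,
                       mean_freq_monotone_decrease = freq_down)
    if (!power_up)
      reasons <- c(reasons, "no transient power increase along eps_ii ramp")
    if (!freq_down)
      reasons <- c(reasons, "mean frequency not monotonically decreasing")
  }
  structure(list(passed = length(reasons) == 0, stable = stable,
                 alpha_peak_hz = peak, low_freq_slope = slope,
                 rates_per_s = rates, reasons = reasons,
                 anesthetic = anesthetic),
            class = "meso_verdict")
}

#' @export
print.meso_verdict <- function(x, ...) {
  cat("<meso_verdict>", if (x$passed) "PASS" else "FAIL", "\n")
  cat(sprintf("  stable: %s; rates: e=%.2f i=%.2f per s; peak %.2f Hz; ",
              x$stable, x$rates_per_s["e"], x$rates_per_s["i"],
              x$alpha_peak_hz))
  cat(sprintf("slope %.2f\n", x$low_freq_slope))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}
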