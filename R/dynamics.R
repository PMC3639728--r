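`%||%` <- function(a, b) if (length(a)) a else b

# Equilibrium of the synaptic cascade for a given presynaptic drive A:
# I* = exp(gamma/gamma0) * Gamma * A / gamma, J* = gamma_tilde * I*.
equilibrium_synaptic <- function(A, P) {
  I <- J <- stats::setNames(numeric(4), SYN)
  for (lk in SYN) {
    gp <- gamma_pair(P$eps[[lk]], P$gamma0[[lk]])
    I[lk] <- exp(gp[["gamma"]] / P$gamma0[[lk]]) * P$Gamma[[lk]] * A[[lk]] /
      gp[["gamma"]]
    J[lk] <- gp[["gamma_tilde"]] * I[lk]
  }
  list(I = I, J = J)
}

# Residual of the equilibrium conditions reduced to (h_e, h_i): all other
# state components are slaved to h at a fixed point.
reduced_residual <- function(h, P) {
  Se <- firing_rate(h[1], "e", P)
  Si <- firing_rate(h[2], "i", P)
  A <- c(ee = P$N_beta[["ee"]] * Se + P$N_alpha[["ee"]] * Se + P$p[["ee"]],
         ei = P$N_beta[["ei"]] * Se + P$N_alpha[["ei"]] * Se + P$p[["ei"]],
         ie = P$N_beta[["ie"]] * Si + P$p[["ie"]],
         ii = P$N_beta[["ii"]] * Si + P$p[["ii"]])
  eq <- equilibrium_synaptic(A, P)
  c(P$h_rest[["e"]] - h[1] + ionic_weight(h[1], "ee", P) * eq$I[["ee"]] +
      ionic_weight(h[1], "ie", P) * eq$I[["ie"]],
    P$h_rest[["i"]] - h[2] + ionic_weight(h[2], "ei", P) * eq$I[["ei"]] +
      ionic_weight(h[2], "ii", P) * eq$I[["ii"]])
}

# Damped Newton on the reduced system; returns (h_e, h_i) or NULL.
reduced_newton <- function(h, P, tol = 1e-13, maxit = 200) {
  for (it in seq_len(maxit)) {
    f0 <- reduced_residual(h, P)
    n0 <- sqrt(sum(f0^2))
    if (!is.finite(n0)) return(NULL)
    if (n0 < tol) return(h)
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      hp <- h; d <- 1e-7 * max(1, abs(h[j])); hp[j] <- hp[j] + d
      Jm[, j] <- (reduced_residual(hp, P) - f0) / d
    }
    dh <- tryCatch(solve(Jm, -f0), error = function(e) NULL)
    if (is.null(dh)) return(NULL)
    lam <- 1
    repeat {
      hn <- h + lam * dh
      if (sqrt(sum(reduced_residual(hn, P)^2)) < n0 || lam < 1e-9) break
      lam <- lam / 2
    }
    if (lam < 1e-9) return(if (n0 < 1e-9) h else NULL)
    h <- hn
  }
  if (sqrt(sum(reduced_residual(h, P)^2)) < 1e-9) h else NULL
}

# Assemble the full 14-component state slaved to equilibrium (h_e, h_i).
state_from_h <- function(h, P) {
  Se <- firing_rate(h[1], "e", P)
  Si <- firing_rate(h[2], "i", P)
  A <- c(ee = P$N_beta[["ee"]] * Se + P$N_alpha[["ee"]] * Se + P$p[["ee"]],
         ei = P$N_beta[["ei"]] * Se + P$N_alpha[["ei"]] * Se + P$p[["ei"]],
         ie = P$N_beta[["ie"]] * Si + P$p[["ie"]],
         ii = P$N_beta[["ii"]] * Si + P$p[["ii"]])
  eq <- equilibrium_synaptic(A, P)
  phi <- P$N_alpha * Se
  psi <- P$v * P$Lambda * phi
  fast_state(h = c(e = h[1], i = h[2]), I = eq$I, J = eq$J,
             phi = stats::setNames(phi, c("ee", "ei")),
             psi = stats::setNames(psi, c("ee", "ei")))
}

#' Jacobian of the fast system at a state
#'
#' Central finite differences of [fast_rhs()].
#'
#' @param P a [model_parameters()] object.
#' @param state a 14-component fast state.
#' @param step relative finite-difference step.
#' @return A 14 x 14 matrix (per-ms rates).
#' @export
fast_jacobian <- function(P, state, step = 1e-6) {
  y <- as.numeric(as_fast_state(state))
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- step * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + d
    ym <- y; ym[j] <- ym[j] - d
    J[, j] <- (fast_rhs(yp, P) - fast_rhs(ym, P)) / (2 * d)
  }
  dimnames(J) <- list(state_names(), state_names())
  J
}

#' Locate a fixed point of the fast system
#'
#' Solves the equilibrium conditions, reduced to the two membrane potentials
#' (all other components are slaved at equilibrium), by damped Newton
#' iteration from a grid of starting points, then verifies the residual of
#' the full 14-dimensional right-hand side and attaches the eigenvalues of
#' the finite-difference Jacobian.
#'
#' @param P a [model_parameters()] object.
#' @param guess optional starting point: a full 14-component state or a
#'   length-2 vector `(h_e, h_i)`; tried before the default grid.
#' @return An object of class `meso_fp`: list with `state` (the fixed
#'   point), `residual` (max absolute rhs, relative to the component
#'   scales), `eigenvalues` (14 complex per-ms values), `stable` (all real
#'   parts negative), `h` (the membrane potentials).
#' @export
find_fixed_point <- function(P, guess = NULL) {
  starts <- list()
  if (!is.null(guess)) {
    g <- as.numeric(guess)
    starts[[1]] <- if (length(g) >= 14) g[1:2] else g[1:2]
  }
  grid <- expand.grid(he = seq(-80, -40, by = 5), hi = seq(-80, -40, by = 5))
  starts <- c(starts, lapply(seq_len(nrow(grid)),
                             function(i) as.numeric(grid[i, ])))
  # collect distinct roots from the multistart; prefer a stable one (the
  # physiological resting state) when several equilibria coexist
  roots <- list()
  for (s in starts) {
    r <- reduced_newton(s, P)
    if (is.null(r)) next
    if (!any(vapply(roots, function(q) max(abs(q - r)) < 1e-6, logical(1))))
      roots[[length(roots) + 1L]] <- r
    if (!is.null(guess) && length(roots)) break  # honor an explicit guess
  }
  if (!length(roots))
    stop("no fixed point found from ", length(starts),
         " starting points on the (h_e, h_i) grid [-80, -40]^2")
  stab <- vapply(roots, function(r) {
    ev <- eigen(fast_jacobian(P, state_from_h(r, P)), only.values = TRUE)$values
    max(Re(ev))
  }, numeric(1))
  stable_roots <- which(stab < 0)
  pick <- if (length(stable_roots)) {
    # most hyperpolarized stable equilibrium = the resting state
    stable_roots[which.min(vapply(stable_roots,
                                  function(i) roots[[i]][1], numeric(1)))]
  } else which.min(stab)
  root <- roots[[pick]]
  state <- state_from_h(root, P)
  rhs <- fast_rhs(state, P)
  scale <- pmax(abs(as.numeric(state)), 1)
  residual <- max(abs(rhs) / scale)
  if (residual > 1e-10)
    stop("fixed-point residual ", signif(residual, 3),
         " exceeds tolerance 1e-10")
  J <- fast_jacobian(P, state)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = state, h = stats::setNames(root, c("e", "i")),
                 residual = residual, eigenvalues = ev,
                 stable = all(Re(ev) < 0), jacobian = J),
            class = "meso_fp")
}

#' @export
print.meso_fp <- function(x, ...) {
  cat(sprintf("<meso_fp> h_e = %.4f mV, h_i = %.4f mV (%s)\n",
              x$h["e"], x$h["i"], if (x$stable) "stable" else "unstable"))
  lead <- x$eigenvalues[which.max(Re(x$eigenvalues))]
  cat(sprintf("  leading eigenvalue: %.5f %+.5fi per ms (%.2f Hz)\n",
              Re(lead), Im(lead), abs(Im(lead)) / (2 * pi) * 1000))
  invisible(x)
}

# |H(2*pi*i*f)|^2 for the linearization (J, b) observed at component `obs`;
# f in Hz, J and b in per-ms units.
transfer_power <- function(J, b, freqs_hz, obs = 1) {
  n <- nrow(J)
  vapply(freqs_hz, function(f) {
    w <- 2 * pi * f / 1000
    x <- solve(1i * w * diag(n) - J, b)
    Mod(x[obs])^2
  }, numeric(1))
}

# Peak frequency of a spectrum: the highest interior local maximum (the
# resonant peak riding on the low-frequency background); global argmax if
# the spectrum has no interior local maximum.
spectral_peak_frequency <- function(freq, power) {
  n <- length(power)
  if (n >= 3) {
    i <- 2:(n - 1)
    loc <- i[power[i] > power[i - 1] & power[i] >= power[i + 1]]
    if (length(loc)) return(freq[loc[which.max(power[loc])]])
  }
  freq[which.max(power)]
}

#' Linearized white-noise fluctuation spectrum
#'
#' Power spectrum of `h_e` for the fast system linearized about its stable
#' fixed point, driven by white noise on one extra-cortical input channel:
#' `power(f) = |H(2 pi i f)|^2`, with `H` the transfer function from the
#' drive to `h_e`, evaluated by solving `(2 pi i f I - J) x = b` on the
#' frequency grid.  Reported per unit drive spectral density, so the result
#' is invariant to rescaling the drive amplitude.
#'
#' The reported peak frequency is the highest *interior local maximum* of
#' the spectrum: resting-EEG-like spectra combine a decaying low-frequency
#' background with a resonant alpha peak, so the global argmax over a grid
#' reaching low frequencies would always sit at the grid edge rather than at
#' the resonance the normative criteria refer to.
#'
#' @param P a [model_parameters()] object.
#' @param drive drive channel, one of `"p_ee"`, `"p_ei"`, `"p_ie"`, `"p_ii"`.
#' @param freqs frequency grid, Hz.
#' @return An object of class `meso_spectrum`: data frame with columns
#'   `frequency` (Hz) and `power` (mV^2 per unit drive density), attributes
#'   `peak_frequency` (Hz) and `low_freq_slope` (log-log slope over 1-7 Hz,
#'   `NA` when the grid does not cover that band).
#' @export
linear_spectrum <- function(P, drive = "p_ee", freqs = seq(0.25, 60, by = 0.25)) {
  drive <- match.arg(drive, paste0("p_", SYN))
  fp <- find_fixed_point(P)
  if (!fp$stable)
    stop("fixed point is unstable; the linearized fluctuation spectrum ",
         "is undefined")
  lk <- sub("^p_", "", drive)
  gp <- gamma_pair(P$eps[[lk]], P$gamma0[[lk]])
  b <- numeric(14)
  b[6 + match(lk, SYN)] <- gp[["gamma_tilde"]] *
    exp(gp[["gamma"]] / P$gamma0[[lk]]) * P$Gamma[[lk]]
  pow <- transfer_power(fp$jacobian, b, freqs, obs = 1)
  band <- freqs >= 1 & freqs <= 7
  slope <- if (sum(band) >= 2)
    unname(stats::coef(stats::lm(log(pow[band]) ~ log(freqs[band])))[2])
  else NA_real_
  structure(data.frame(frequency = freqs, power = pow),
            peak_frequency = spectral_peak_frequency(freqs, pow),
            low_freq_slope = slope,
            drive = drive,
            class = c("meso_spectrum", "data.frame"))
}

#' @export
print.meso_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<meso_spectrum> drive %s, %d frequencies in ",
                     "[%g, %g] Hz\n  peak %.2f Hz, 1-7 Hz log-log slope ",
                     "%.2f\n"),
              attr(x, "drive"), nrow(x), min(x$frequency), max(x$frequency),
              attr(x, "peak_frequency"), attr(x, "low_freq_slope")))
  invisible(x)
}

#' One-parameter continuation of fixed points
#'
#' Natural-parameter continuation of the fast system's fixed-point locus
#' over a grid of values of any scalar model parameter, warm-starting each
#' solve from the previous solution (with adaptive sub-stepping through
#' steep segments).  Stability is flagged per point from the Jacobian
#' eigenvalues, and each stability change bracketed by the grid is refined
#' by bisection on the leading eigenvalue's real part; crossings with
#' nonzero imaginary part are reported as Hopf points.
#'
#' @param P a [model_parameters()] object (the branch starts from this
#'   configuration with `parameter` set to `range[1]`).
#' @param parameter scalar parameter symbol, e.g. `"Gamma_ii"` (see
#'   [param_value()]).
#' @param range `c(lo, hi)` parameter interval.
#' @param steps number of grid points.
#' @param hopf_tol bisection tolerance as a fraction of the range width.
#' @return An object of class `meso_branch`: list with `parameter`, `values`
#'   (grid actually covered), `h` (two-column matrix of equilibrium membrane
#'   potentials), `states`, `stable` (logical), `max_re` (leading real
#'   part), `freq_hz` (leading imaginary part as a frequency), `hopf`
#'   (data frame of refined crossings: value, real part, frequency, period),
#'   and `complete` (`FALSE` when the branch was lost before covering the
#'   grid).
#' @export
continue_fixed_points <- function(P, parameter, range, steps = 41,
                                  hopf_tol = 1e-4) {
  stopifnot(length(range) == 2, steps >= 2)
  grid <- seq(range[1], range[2], length.out = steps)
  eig_at <- function(val, h_start) {
    Pv <- set_param_value(P, parameter, val)
    root <- reduced_newton(h_start, Pv)
    if (is.null(root)) return(NULL)
    st <- state_from_h(root, Pv)
    ev <- eigen(fast_jacobian(Pv, st), only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    list(h = root, state = st, lead = lead, ev = ev)
  }
  # first point: solve from scratch
  P1 <- set_param_value(P, parameter, grid[1])
  fp1 <- find_fixed_point(P1)
  h <- as.numeric(fp1$h)

  values <- numeric(0); hs <- NULL; states <- list()
  stable <- logical(0); max_re <- numeric(0); freq <- numeric(0)
  complete <- TRUE
  cur <- grid[1]
  for (i in seq_along(grid)) {
    target <- grid[i]
    # adaptive sub-stepping from cur to target
    ok <- TRUE
    while (abs(target - cur) > 0) {
      step <- target - cur
      sol <- NULL
      for (halvings in 0:12) {
        sol <- eig_at(cur + step, h)
        if (!is.null(sol)) break
        step <- step / 2
      }
      if (is.null(sol)) { ok <- FALSE; break }
      cur <- cur + step
      h <- sol$h
    }
    if (!ok) sol <- if (cur > (values[length(values)] %||% -Inf))
      eig_at(cur, h) else NULL
    else sol <- eig_at(target, h)
    if (is.null(sol)) { complete <- FALSE; break }
    values <- c(values, if (ok) target else cur)
    hs <- rbind(hs, sol$h)
    states[[length(states) + 1L]] <- sol$state
    stable <- c(stable, max(Re(sol$ev)) < 0)
    max_re <- c(max_re, Re(sol$lead))
    freq <- c(freq, abs(Im(sol$lead)) / (2 * pi) * 1000)
    if (!ok) { complete <- FALSE; break }
  }

  # refine stability changes by bisection on the leading real part
  hopf <- data.frame(value = numeric(0), re = numeric(0),
                     frequency_hz = numeric(0), period_ms = numeric(0))
  tol <- hopf_tol * abs(diff(range))
  if (length(values) >= 2) {
    for (i in seq_len(length(values) - 1)) {
      if (stable[i] == stable[i + 1]) next
      lo <- values[i]; hi <- values[i + 1]; hlo <- hs[i, ]
      lead_hi <- NULL
      while (abs(hi - lo) > tol) {
        mid <- (lo + hi) / 2
        sol <- eig_at(mid, hlo)
        if (is.null(sol)) break
        if ((Re(sol$lead) < 0) == stable[i]) {
          lo <- mid; hlo <- sol$h
        } else {
          hi <- mid; lead_hi <- sol$lead
        }
      }
      sol <- eig_at((lo + hi) / 2, hlo)
      lead <- if (!is.null(sol)) sol$lead else lead_hi
      if (is.null(lead)) next
      f_hz <- abs(Im(lead)) / (2 * pi) * 1000
      if (abs(Im(lead)) > 0) {
        period <- 2 * pi / abs(Im(lead))
        if (period < 1 || period > 1000)
          warning(sprintf(paste0("Hopf crossing at %s = %.5f has period ",
                                 "%.1f ms outside the physiological range ",
                                 "1-1000 ms"), parameter, (lo + hi) / 2,
                          period), call. = FALSE)
        hopf <- rbind(hopf, data.frame(value = (lo + hi) / 2,
                                       re = Re(lead), frequency_hz = f_hz,
                                       period_ms = period))
      }
    }
  }
  structure(list(parameter = parameter, values = values, h = hs,
                 states = states, stable = stable, max_re = max_re,
                 freq_hz = freq, hopf = hopf, complete = complete),
            class = "meso_branch")
}

#' @export
print.meso_branch <- function(x, ...) {
  cat(sprintf("<meso_branch> %s over [%g, %g], %d points%s\n",
              x$parameter, min(x$values), max(x$values), length(x$values),
              if (x$complete) "" else " (branch lost before end of grid)"))
  if (nrow(x$hopf)) {
    for (i in seq_len(nrow(x$hopf)))
      cat(sprintf("  Hopf at %s = %.5f (%.2f Hz)\n", x$parameter,
                  x$hopf$value[i], x$hopf$frequency_hz[i]))
  } else cat("  no Hopf points detected\n")
  invisible(x)
}

#' Write a continuation branch to CSV
#'
#' One row per branch point: parameter value, equilibrium membrane
#' potentials, leading real part and stability flag.
#'
#' @param branch a `meso_branch`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_branch <- function(branch, path) {
  df <- data.frame(value = branch$values,
                   h_e = branch$h[, 1], h_i = branch$h[, 2],
                   max_re = branch$max_re, freq_hz = branch$freq_hz,
                   stable = branch$stable)
  names(df)[1] <- branch$parameter
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Bistability probe by bidirectional parameter sweep
#'
#' Sweeps a scalar parameter across a grid in both directions, integrating
#' to steady behavior at each value while warm-starting from the previous
#' value's end state, and classifies the attractor reached by the
#' peak-to-peak amplitude of `h_e` over the final analysis window.  A
#' parameter window where the ascending and descending classifications
#' differ signals the coexistence of a fixed point with a large-amplitude
#' oscillation (the hysteresis loop that fast-slow bursting traverses).
#'
#' @param P a [model_parameters()] object.
#' @param parameter scalar parameter symbol.
#' @param values parameter grid (ascending order; the descending sweep
#'   reverses it).
#' @param settle integration time per value before classification, ms.
#' @param window final span used for the amplitude measurement, ms.
#' @param threshold peak-to-peak amplitude (mV) above which the attractor is
#'   classified as an oscillation.
#' @param dt integration step, ms.
#' @return Data frame with one row per grid value: `value`, peak-to-peak
#'   amplitudes `amp_up` / `amp_down`, classifications `up` / `down`
#'   (`"fixed-point"` or `"oscillation"`), and `bistable`.
#' @export
hysteresis_probe <- function(P, parameter, values, settle = 3000,
                             window = 1000, threshold = 1, dt = 0.1) {
  values <- sort(values)
  run_dir <- function(vals) {
    amps <- numeric(length(vals))
    init <- NULL
    for (i in seq_along(vals)) {
      Pv <- set_param_value(P, parameter, vals[i])
      if (is.null(init)) {
        init <- tryCatch(find_fixed_point(Pv)$state, error = function(e)
          fast_state(h = c(e = Pv$h_rest[["e"]], i = Pv$h_rest[["i"]])))
        # nudge off the equilibrium so an unstable fixed point does not
        # masquerade as an attractor
        init[1] <- init[1] + 0.5
      }
      st <- sim_settings(duration = settle, dt = dt, record_dt = 1,
                         transient_discard = settle - window)
      ts <- simulate_model(Pv, settings = st, init = init)
      amps[i] <- diff(range(ts$h_e))
      init <- as.numeric(ts[nrow(ts), setdiff(names(ts), "t")])
    }
    amps
  }
  amp_up <- run_dir(values)
  amp_down <- rev(run_dir(rev(values)))
  cls <- function(a) ifelse(a > threshold, "oscillation", "fixed-point")
  data.frame(value = values, amp_up = amp_up, amp_down = amp_down,
             up = cls(amp_up), down = cls(amp_down),
             bistable = cls(amp_up) != cls(amp_down))
}
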