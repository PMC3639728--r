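#' Simulation settings
#'
#' @param duration total integration time, ms.
#' @param dt integration step of the fixed-step solver, ms (default 0.1 ms,
#'   the reference scheme's step).
#' @param solver `"rk4_fixed"` (classical 4th-order Runge-Kutta at `dt`) or
#'   `"stiff_adaptive"` (adaptive multistep integration with error control,
#'   resampled to the uniform output grid).
#' @param transient_discard initial span removed from the returned series, ms.
#' @param record_dt output sampling interval, ms; must be a multiple of `dt`
#'   for the fixed-step solver.  Stored samples are instantaneous values.
#' @param noise optional stochastic extra-cortical drive,
#'   `list(target = "p_ee", sd = ..., seed = ...)`: an additive white
#'   perturbation of the chosen tonic rate, applied Euler-Maruyama style at
#'   each step (per-step value `sd/sqrt(dt) * N(0,1)`, so the perturbation
#'   has flat spectral density `sd^2` in per-ms units).  Default off; the
#'   deterministic bursting runs use no noise.
#' @param rtol,atol tolerances of the stiff solver.
#' @return A list of class `meso_settings`.
#' @export
sim_settings <- function(duration, dt = 0.1,
                         solver = c("rk4_fixed", "stiff_adaptive"),
                         transient_discard = 0, record_dt = 1,
                         noise = NULL, rtol = 1e-8, atol = 1e-8) {
  solver <- match.arg(solver)
  stopifnot(duration > dt, dt > 0, transient_discard < duration,
            record_dt >= dt)
  if (!is.null(noise)) {
    stopifnot(is.list(noise), noise$target %in% paste0("p_", SYN),
              is.numeric(noise$sd), noise$sd >= 0)
  }
  structure(list(duration = duration, dt = dt, solver = solver,
                 transient_discard = transient_discard,
                 record_dt = record_dt, noise = noise,
                 rtol = rtol, atol = atol),
            class = "meso_settings")
}

#' Default initial state of the fast system
#'
#' The fixed point of the fast system when one can be located; otherwise the
#' resting-potential state with zeroed synaptic and flux components, with a
#' warning.  Repeated calls are identical.
#'
#' @param P a [model_parameters()] object.
#' @return A `meso_state` (14 components).
#' @export
default_initial_state <- function(P) {
  fp <- tryCatch(find_fixed_point(P), error = function(e) NULL)
  if (!is.null(fp)) return(fp$state)
  warning("no fixed point found; falling back to the resting-potential ",
          "state with zeroed synaptic components", call. = FALSE)
  fast_state(h = c(e = P$h_rest[["e"]], i = P$h_rest[["i"]]))
}

#' Integrate the (coupled) model
#'
#' Numerically integrates the fast EEG system, optionally coupled to a slow
#' synaptic-depression system, and returns a uniformly sampled multichannel
#' time series.  Deterministic given identical inputs (and noise seed).
#'
#' @param P a [model_parameters()] object.
#' @param slow a [slow_config()] (or `NULL` for the pure fast system).
#'   Run-time defaults (SS2 thresholds anchored at the unmodulated fixed
#'   point, initial amplitudes at the model's resting values) are resolved
#'   here.
#' @param settings a [sim_settings()] object.
#' @param init initial fast state; default [default_initial_state()].
#' @param slow_init optional named initial amplitudes overriding the
#'   configuration's defaults (mV).
#' @return A data frame of class `meso_ts` with column `t` (ms) and one
#'   column per state component (`h_e`, `h_i`, `I_*`, `J_*`, `phi_*`,
#'   `psi_*`, and `Gamma_<lk>` for each modulated synapse).  Attribute
#'   `record_dt` gives the sampling interval.
#' @export
simulate_model <- function(P, slow = NULL, settings, init = NULL,
                           slow_init = NULL) {
  stopifnot(inherits(P, "meso_params"), inherits(settings, "meso_settings"))
  slow <- resolve_slow(slow, P)
  if (is.null(init)) init <- default_initial_state(P)
  y0 <- as.numeric(as_fast_state(init))
  slow_cols <- character(0)
  if (!is.null(slow)) {
    g0 <- slow$Gamma_init
    if (!is.null(slow_init)) g0[names(slow_init)] <- as.numeric(slow_init)
    y0 <- c(y0, unname(g0[slow$targets]))
    slow_cols <- paste0("Gamma_", slow$targets)
  }
  pv <- param_engine_vector(P, slow)
  cols <- c("t", state_names(), slow_cols)

  if (settings$solver == "rk4_fixed") {
    rec_every <- round(settings$record_dt / settings$dt)
    if (abs(rec_every * settings$dt - settings$record_dt) > 1e-9)
      stop("record_dt must be a multiple of dt for the fixed-step solver")
    nstep <- ceiling(settings$duration / settings$dt)
    noise <- numeric(0); noise_slot <- -1L
    if (!is.null(settings$noise) && settings$noise$sd > 0) {
      noise_slot <- match(settings$noise$target, paste0("p_", SYN)) - 1L
      noise <- with_seed(settings$noise$seed,
                         stats::rnorm(nstep, sd = settings$noise$sd /
                                        sqrt(settings$dt)))
    }
    res <- .engine_rk4(y0, pv, settings$dt, nstep, rec_every, noise,
                       noise_slot, 500)
    if (res$bad_time >= 0)
      stop(sprintf(paste0("solution left the sanity envelope ",
                          "(|h| > 500 mV or non-finite) at t = %.4f ms"),
                   res$bad_time))
    tr <- res$trace[seq_len(res$n_recorded), , drop = FALSE]
  } else {
    if (!is.null(settings$noise) && settings$noise$sd > 0)
      stop("stochastic drive requires the rk4_fixed solver")
    times <- seq(0, settings$duration, by = settings$record_dt)
    sol <- deSolve::ode(y = y0, times = times, func = "mesoburst_derivs",
                        parms = pv, dllname = "mesoburst",
                        initfunc = "mesoburst_initmod",
                        method = "lsoda",
                        rtol = settings$rtol, atol = settings$atol)
    tr <- unclass(sol)
    if (any(!is.finite(tr)) || any(abs(tr[, 2]) > 500) ||
        any(abs(tr[, 3]) > 500)) {
      ibad <- which(rowSums(!is.finite(tr)) > 0 | abs(tr[, 2]) > 500 |
                      abs(tr[, 3]) > 500)[1]
      stop(sprintf(paste0("solution left the sanity envelope ",
                          "(|h| > 500 mV or non-finite) at t = %.4f ms"),
                   tr[ibad, 1]))
    }
  }

  df <- as.data.frame(tr)
  names(df) <- cols
  df <- df[df$t >= settings$transient_discard, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, record_dt = settings$record_dt,
            slow_targets = if (is.null(slow)) character(0) else slow$targets,
            class = c("meso_ts", "data.frame"))
}

# evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Write a simulated time series to CSV
#'
#' Plain CSV with a leading comment line stating the units (time in ms,
#' potentials in mV, fluxes per ms), then a header row.
#'
#' @param ts a `meso_ts` object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "meso_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: t ms; h_*, I_*, Gamma_* mV; J_* mV/ms; ",
                    "phi_* 1/ms; psi_* 1/ms^2"), con)
  utils::write.csv(as.data.frame(ts), con, row.names = FALSE)
  invisible(path)
}

#' @export
print.meso_ts <- function(x, ...) {
  cat(sprintf("<meso_ts> %d samples at %g ms, t in [%g, %g] ms, channels: %s\n",
              nrow(x), attr(x, "record_dt"), min(x$t), max(x$t),
              paste(setdiff(names(x), "t"), collapse = ", ")))
  invisible(x)
}
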