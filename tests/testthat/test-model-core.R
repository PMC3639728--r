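test_that("firing rate is half-maximal at threshold and respects sigmoid limits", {
  P <- tbl3()
  expect_equal(firing_rate(P$mu_bar[["e"]], "e", P), 0.2801 / 2)
  expect_equal(firing_rate(P$mu_bar[["i"]], "i", P), 0.1228 / 2)
  expect_equal(firing_rate(-1e6, "e", P), 0)
  expect_equal(firing_rate(1e6, "e", P), P$S_max[["e"]])
  # one threshold-spread above threshold: closed-form sigmoid value
  h <- P$mu_bar[["i"]] + P$sigma[["i"]]
  expect_equal(firing_rate(h, "i", P),
               P$S_max[["i"]] / (1 + exp(-sqrt(2))), tolerance = 1e-12)
  expect_error(firing_rate(NaN, "e", P), "non-finite")
})

test_that("firing rate is strictly increasing and bounded on [-100, 0] mV", {
  P <- tbl3()
  h <- seq(-100, 0, by = 0.5)
  for (pop in c("e", "i")) {
    s <- firing_rate(h, pop, P)
    expect_true(all(diff(s) > 0))
    expect_true(all(s > 0 & s < P$S_max[[pop]]))
  }
})

test_that("gamma_pair has the analytic eps -> 0 limit and ordering", {
  gp <- gamma_pair(0, 0.0782)
  expect_identical(unname(gp), c(0.0782, 0.0782))
  gp <- gamma_pair(1, 0.1)
  expect_equal(gp[["gamma"]], 0.1 / (exp(1) - 1), tolerance = 1e-14)
  expect_equal(gp[["gamma_tilde"]], 0.1 * exp(1) / (exp(1) - 1),
               tolerance = 1e-14)
  # gamma < gamma0 < gamma_tilde for every positive eps
  for (eps in seq(0.05, 5, by = 0.05)) {
    gp <- gamma_pair(eps, 0.2)
    expect_lt(gp[["gamma"]], 0.2)
    expect_gt(gp[["gamma_tilde"]], 0.2)
    expect_equal(gp[["gamma_tilde"]], gp[["gamma"]] * exp(eps))
  }
  expect_error(gamma_pair(-0.1, 0.1), "eps")
  expect_error(gamma_pair(0.1, 0), "gamma0")
})

test_that("unitary PSP reduces to the alpha function and peaks at 1/gamma0", {
  g0 <- 0.0782; G <- 1.4122
  expect_equal(unitary_psp(1 / g0, G, g0, eps = 0), G)
  expect_identical(unitary_psp(-5, G, g0), 0)
  expect_identical(unitary_psp(0, G, g0), 0)
  expect_lt(unitary_psp(200 / g0, G, g0), 1e-12)
  # near-critically-damped limit matches the alpha function to 1e-6 relative
  t <- seq(0.01, 10 / g0, length.out = 400)
  alpha <- G * g0 * t * exp(1 - g0 * t)
  expect_rel_equal(unitary_psp(t, G, g0, eps = 1e-9), alpha, 1e-6)
  # peak amplitude G at t = 1/gamma0 for all decay shapes (analytic form)
  for (eps in c(0, 0.5, 1.8, 3)) {
    expect_equal(unitary_psp(1 / g0, G, g0, eps), G, tolerance = 1e-12)
    tg <- seq(0.05, 5 / g0, by = 0.05)
    v <- unitary_psp(tg, G, g0, eps)
    expect_lt(abs(tg[which.max(v)] - 1 / g0), 0.05 + 1e-9)
  }
})

test_that("unitary PSP matches the impulse response of the two-stage cascade", {
  # independent oracle: integrate the cascade ODE driven by a unit impulse
  G <- 1; g0 <- 0.1; eps <- 2
  gp <- gamma_pair(eps, g0)
  D <- gp[["gamma_tilde"]] * exp(gp[["gamma"]] / g0) * G
  deriv <- function(t, y, parms) {
    list(c(y[2] - gp[["gamma_tilde"]] * y[1], -gp[["gamma"]] * y[2]))
  }
  times <- seq(0, 200, by = 0.05)
  sol <- deSolve::ode(y = c(I = 0, J = D), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  expect_rel_equal(unitary_psp(times[-1], G, g0, eps), sol[-1, "I"], 1e-6)
  # half-decay of the tail: time past the peak where the PSP falls to G/2
  tail_t <- times[times > 1 / g0]
  t_half_num <- tail_t[which.min(abs(sol[times > 1 / g0, "I"] - G / 2))]
  t_half_ana <- tail_t[which.min(abs(unitary_psp(tail_t, G, g0, eps) - G / 2))]
  expect_equal(t_half_ana, t_half_num, tolerance = 0.06)
  # longer decay shape factor means slower tail decay
  expect_gt(unitary_psp(60, G, g0, eps = 3), unitary_psp(60, G, g0, eps = 1))
})

test_that("synaptic drive assembles local, long-range and tonic input", {
  P <- tbl3()
  # silent network: all firing suppressed, no flux, no tonic input
  P0 <- P; P0$p[] <- 0
  silent <- fast_state(h = c(e = -2000, i = -2000))
  expect_identical(unname(synaptic_drive(silent, P0)), rep(0, 4))
  # at the fixed point the drive matches an independent hand evaluation
  fp <- tbl3_fp()
  Se <- firing_rate(fp$h[["e"]], "e", P)
  Si <- firing_rate(fp$h[["i"]], "i", P)
  manual <- c(ee = P$N_beta[["ee"]] * Se + P$N_alpha[["ee"]] * Se + P$p[["ee"]],
              ei = P$N_beta[["ei"]] * Se + P$N_alpha[["ei"]] * Se + P$p[["ei"]],
              ie = P$N_beta[["ie"]] * Si,
              ii = P$N_beta[["ii"]] * Si)
  expect_equal(synaptic_drive(fp$state, P), manual, tolerance = 1e-12)
  # the excitatory extra-cortical rate is a lower bound on A_ee
  expect_gte(synaptic_drive(fp$state, P)[["ee"]], 3.6032)
  expect_error(synaptic_drive(fp$state, P, p_override = c(1, 2)), "p_override")
})

test_that("fast rhs vanishes at equilibria and is continuous at eps -> 0", {
  P <- tbl3()
  fp <- tbl3_fp()
  r <- fast_rhs(fp$state, P)
  expect_lt(max(abs(r) / pmax(abs(as.numeric(fp$state)), 1)), 1e-10)
  # decoupled resting state: firing fully suppressed, no input
  Pq <- model_parameters(mu_bar = c(e = 2000, i = 2000),
                         p = c(ee = 0, ei = 0, ie = 0, ii = 0),
                         check_ranges = FALSE)
  rest <- fast_state(h = c(e = Pq$h_rest[["e"]], i = Pq$h_rest[["i"]]))
  expect_identical(unname(fast_rhs(rest, Pq)), rep(0, 14))
  # extended kinetics converge to the critically damped branch
  y <- as.numeric(fp$state) + 0.3
  P1 <- P; P1$eps[] <- 1e-12
  expect_rel_equal(fast_rhs(y, P1), fast_rhs(y, P), 1e-6)
  expect_error(fast_rhs(rep(NaN, 14), P), "non-finite")
})

test_that("compiled right-hand side agrees exactly with the R reference", {
  P <- tbl3()
  fp <- tbl3_fp()
  pv <- mesoburst:::param_engine_vector(P, NULL)
  set.seed(7)
  for (i in 1:10) {
    y <- as.numeric(fp$state) * (1 + stats::rnorm(14, sd = 0.05))
    expect_identical(mesoburst:::.engine_rhs(y, pv), unname(fast_rhs(y, P)))
  }
  # with a slow system attached (both laws)
  for (preset in c("fig3", "fig6")) {
    slow <- resolve_slow(preset_slow(preset), P)
    pv <- mesoburst:::param_engine_vector(P, slow)
    g <- slow$Gamma_init
    y <- as.numeric(fp$state)
    d <- mesoburst:::.engine_rhs(c(y, unname(g)), pv)
    ref <- coupled_rhs(y, g, P, slow)
    expect_equal(d[1:14], unname(ref$fast), tolerance = 1e-14)
    expect_equal(d[-(1:14)], unname(ref$slow[slow$targets]), tolerance = 1e-14)
  }
  slow2 <- fig7_slow()
  P7 <- fig7_model()
  pv <- mesoburst:::param_engine_vector(P7, slow2)
  g <- slow2$Gamma_init * 0.7
  y <- as.numeric(find_fixed_point(P7)$state) + 0.2
  d <- mesoburst:::.engine_rhs(c(y, unname(g)), pv)
  ref <- coupled_rhs(y, g, P7, slow2)
  expect_equal(d[1:14], unname(ref$fast), tolerance = 1e-14)
  expect_equal(d[-(1:14)], unname(ref$slow[slow2$targets]), tolerance = 1e-14)
})

test_that("trajectories stay within the reversal-potential envelope", {
  P <- tbl3()
  lims <- range(c(P$h_eq, P$h_rest))
  set.seed(11)
  for (i in 1:4) {
    init <- fast_state(h = c(e = stats::runif(1, -75, -50),
                             i = stats::runif(1, -75, -50)))
    ts <- simulate_model(P, settings = sim_settings(duration = 2000, dt = 0.1,
                                                    record_dt = 1,
                                                    transient_discard = 500),
                         init = init)
    expect_true(all(ts$h_e > lims[1] - 1 & ts$h_e < lims[2] + 1))
    expect_true(all(ts$h_i > lims[1] - 1 & ts$h_i < lims[2] + 1))
  }
})

test_that("parameter validation enforces reversal ordering and positivity", {
  expect_error(model_parameters(h_eq = c(ee = -70, ei = 7.4, ie = -86,
                                         ii = -84.5)),
               "h_eq_ee")
  expect_error(model_parameters(h_eq = c(ee = -15.9, ei = 7.4, ie = -60,
                                         ii = -84.5)),
               "h_eq_ie")
  expect_error(model_parameters(tau = c(e = -1, i = 89)), "must be > 0")
  expect_error(model_parameters(eps = c(ee = -0.1, ei = 0, ie = 0, ii = 0)),
               "eps")
  expect_warning(model_parameters(tau = c(e = 2, i = 89.3207),
                                  check_ranges = TRUE),
                 "admissible")
})

test_that("parameter files round-trip bit-identically", {
  path <- withr::local_tempfile(fileext = ".yaml")
  for (preset in c("table3", "fig7")) {
    P <- preset_model(preset)
    write_parameters(P, path)
    P2 <- read_parameters(path, check_ranges = FALSE)
    for (sym in mesoburst:::param_symbols())
      expect_identical(param_value(P, sym), param_value(P2, sym))
    expect_identical(P$sigmoid_slope, P2$sigmoid_slope)
  }
  # the packaged reference file reproduces the preset exactly
  pkg <- system.file("extdata", "table3.yaml", package = "mesoburst")
  P3 <- read_parameters(pkg, check_ranges = FALSE)
  for (sym in mesoburst:::param_symbols())
    expect_identical(param_value(tbl3(), sym), param_value(P3, sym))
})

test_that("scalar parameter symbols address every field", {
  P <- tbl3()
  expect_equal(param_value(P, "Gamma_ii"), 1.4122)
  expect_equal(param_value(P, "N_beta_ie"), 989.5281)
  P2 <- set_param_value(P, "eps_ii", 1.8)
  expect_equal(P2$eps[["ii"]], 1.8)
  expect_error(param_value(P, "nonsense_xx"), "unknown|symbol")
})
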