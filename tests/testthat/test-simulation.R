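test_that("RK4 reproduces the closed-form membrane decay of the decoupled model", {
  # with zero synaptic amplitudes and no input, each potential relaxes
  # exponentially to rest: dh/dt = (h_rest - h)/tau
  P <- model_parameters(Gamma = c(ee = 0, ei = 0, ie = 0, ii = 0),
                        p = c(ee = 0, ei = 0, ie = 0, ii = 0),
                        check_ranges = FALSE)
  init <- fast_state(h = c(e = P$h_rest[["e"]] + 10, i = P$h_rest[["i"]] + 10))
  ts <- simulate_model(P, settings = sim_settings(duration = 1000, dt = 0.1,
                                                  record_dt = 1),
                       init = init)
  exact <- P$h_rest[["e"]] + 10 * exp(-ts$t / P$tau[["e"]])
  expect_lt(max(abs(ts$h_e - exact)), 1e-10)
})

test_that("halving the step barely changes the solution (4th-order convergence)", {
  P <- tbl3()
  init <- as.numeric(tbl3_fp()$state) + 0.5
  run <- function(dt) simulate_model(P, settings = sim_settings(
    duration = 1000, dt = dt, record_dt = 1), init = init)
  a <- run(0.1); b <- run(0.05)
  expect_lt(sqrt(mean((a$h_e - b$h_e)^2)), 1e-4)
})

test_that("a perturbed start relaxes back to the stable fixed point", {
  P <- tbl3()
  fp <- tbl3_fp()
  init <- as.numeric(fp$state) + c(2, 2, rep(0.5, 12))
  ts <- simulate_model(P, settings = sim_settings(duration = 30000, dt = 0.1,
                                                  record_dt = 10), init = init)
  n <- nrow(ts)
  expect_lt(abs(ts$h_e[n] - fp$h[["e"]]), 1e-3)
  expect_lt(abs(ts$h_i[n] - fp$h[["i"]]), 1e-3)
})

test_that("reruns are bit-identical, with and without seeded noise", {
  P <- tbl3()
  st <- sim_settings(duration = 2000, dt = 0.1, record_dt = 1)
  expect_identical(simulate_model(P, settings = st),
                   simulate_model(P, settings = st))
  stn <- sim_settings(duration = 2000, dt = 0.1, record_dt = 1,
                      noise = list(target = "p_ee", sd = 0.3, seed = 99))
  a <- simulate_model(P, settings = stn)
  b <- simulate_model(P, settings = stn)
  expect_identical(a, b)
  # different seed, different path
  stn2 <- sim_settings(duration = 2000, dt = 0.1, record_dt = 1,
                       noise = list(target = "p_ee", sd = 0.3, seed = 100))
  expect_false(identical(a$h_e, simulate_model(P, settings = stn2)$h_e))
})

test_that("the integrator reports where the solution leaves the sanity envelope", {
  # runaway configuration: positive-feedback excitatory loop with enormous
  # amplitude and no effective reversal saturation
  P <- model_parameters(h_eq = c(ee = 1e5, ei = 1e5, ie = -86, ii = -84.5),
                        Gamma = c(ee = 1e5, ei = 0, ie = 0, ii = 0),
                        check_ranges = FALSE)
  init <- fast_state(h = c(e = P$h_rest[["e"]], i = P$h_rest[["i"]]))
  expect_error(simulate_model(P, settings = sim_settings(duration = 5000,
                                                         dt = 0.1,
                                                         record_dt = 1),
                              init = init),
               "sanity envelope.*t = ")
})

test_that("default initial state is the fixed point, idempotently", {
  P <- tbl3()
  s1 <- default_initial_state(P)
  s2 <- default_initial_state(P)
  expect_identical(s1, s2)
  r <- fast_rhs(s1, P)
  expect_lt(max(abs(r)), 1e-8)
  # when no fixed point can be located the resting state is returned
  testthat::local_mocked_bindings(
    find_fixed_point = function(P, guess = NULL) stop("no fixed point"))
  expect_warning(s3 <- default_initial_state(P), "resting")
  expect_equal(unname(s3[1:2]), unname(P$h_rest))
  expect_identical(unname(s3[3:14]), rep(0, 12))
})

test_that("stiff adaptive integration matches fixed-step RK4", {
  P <- tbl3()
  slow <- preset_slow("fig3")
  a <- simulate_model(P, slow, sim_settings(duration = 5000, dt = 0.1,
                                            record_dt = 1))
  b <- simulate_model(P, slow, sim_settings(duration = 5000,
                                            solver = "stiff_adaptive",
                                            record_dt = 1,
                                            rtol = 1e-10, atol = 1e-10))
  expect_equal(nrow(a), nrow(b))
  expect_lt(sqrt(mean((a$h_e - b$h_e)^2)), 1e-3)
})

test_that("settings are validated and transients discarded", {
  expect_error(sim_settings(duration = 1, dt = 2), "duration")
  expect_error(sim_settings(duration = 100, dt = 1, transient_discard = 200),
               "transient")
  expect_error(sim_settings(duration = 100, noise = list(target = "q_ee",
                                                         sd = 1)),
               "target")
  P <- tbl3()
  ts <- simulate_model(P, settings = sim_settings(duration = 1000, dt = 0.1,
                                                  record_dt = 1,
                                                  transient_discard = 400))
  expect_gte(min(ts$t), 400)
  expect_equal(diff(ts$t), rep(1, nrow(ts) - 1))
})

test_that("time-series CSV writer emits a units header and all channels", {
  P <- tbl3()
  ts <- simulate_model(P, settings = sim_settings(duration = 100, dt = 0.1,
                                                  record_dt = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts, path)
  lines <- readLines(path, n = 2)
  expect_match(lines[1], "^# units")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(names(back), names(ts))
  expect_equal(back$h_e, ts$h_e, tolerance = 1e-12)
})
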