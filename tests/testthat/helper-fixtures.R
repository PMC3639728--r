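# shared fixtures; expensive simulations are computed once per test run
fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

tbl3 <- function() preset_model("table3")

tbl3_fp <- function() memo("tbl3_fp", find_fixed_point(tbl3()))

# the canonical recurrent-bursting run: 60 s analyzed after a 10 s transient
fig3_run <- function() memo("fig3_run", {
  simulate_model(tbl3(), preset_slow("fig3"),
                 sim_settings(duration = 70000, dt = 0.1, record_dt = 1,
                              transient_discard = 10000))
})

fig3_stats <- function() memo("fig3_stats", {
  ts <- fig3_run()
  seg <- segment_bursts(ts)
  list(seg = seg, stats = burst_statistics(seg, ts))
})

fig7_model <- function() preset_model("fig7")

# SS2 slow system with thresholds frozen at the fig7 fast system's fixed point
fig7_slow <- function() memo("fig7_slow",
                             resolve_slow(preset_slow("fig7"), fig7_model()))

# a synthetic uniformly sampled series wrapped as a meso_ts
make_ts <- function(x, dt = 1) {
  df <- data.frame(t = seq_along(x) * dt - dt, h_e = x)
  structure(df, record_dt = dt, slow_targets = character(0),
            class = c("meso_ts", "data.frame"))
}

# amplitude-modulated tone: `cycles` repetitions of 1 s on / 1 s off
am_tone <- function(freq = 10, cycles = 10, dt = 1) {
  t <- seq(0, cycles * 2000 - dt, by = dt)
  on <- (t %/% 1000) %% 2 == 0
  make_ts(sin(2 * pi * freq * t / 1000) * on, dt = dt)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)))
}
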