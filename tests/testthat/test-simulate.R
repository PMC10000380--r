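test_that("ZOH discretization reproduces first-order closed forms and DC gains", {
  blk <- discretize(rtf(1, c(1, 1)), 1e-3)
  expect_equal(step_constant(blk, 1, 10001), 1, tolerance = 1e-3)
  # printed gas-exchange block settles at its DC gain 62/67
  blk <- discretize(gas_exchange_tf(), 1e-3)
  expect_equal(step_constant(blk, 1, 60001), 62 / 67, tolerance = 1e-3)
  expect_error(discretize(rtf(1, c(1, 1)), 0), "dt")
})

test_that("delay lines shift exactly, pad with zeros, and compose additively", {
  dt <- 1e-3
  dl <- delay_line(0, dt)
  expect_equal(delay_step(dl, 7)$y, 7)        # identity
  dl <- delay_line(0.30, dt)
  expect_equal(dl$n, 300L)
  # unit pulse at t = 0 emerges at t = 0.30
  pulse <- c(1, rep(0, 500))
  out <- numeric(length(pulse))
  for (k in seq_along(pulse)) {
    s <- delay_step(dl, pulse[k]); dl <- s$dl; out[k] <- s$y
  }
  expect_equal(which(out == 1), 301L)
  expect_true(all(out[1:300] == 0))
  # composing 0.2 s and 0.3 s equals one 0.5 s line
  set.seed(11)
  x <- rnorm(800)
  d1 <- delay_line(0.2, dt); d2 <- delay_line(0.3, dt)
  d5 <- delay_line(0.5, dt)
  two <- one <- numeric(800)
  for (k in 1:800) {
    s <- delay_step(d1, x[k]); d1 <- s$dl
    s <- delay_step(d2, s$y); d2 <- s$dl
    two[k] <- s$y
    s <- delay_step(d5, x[k]); d5 <- s$dl
    one[k] <- s$y
  }
  expect_identical(two, one)
  # rounding to the nearest sample is reported
  dl <- delay_line(0.2996, dt)
  expect_equal(dl$n, 300L)
  expect_equal(dl$d_actual, 0.3)
})

test_that("scenario validation enforces the physical invariants", {
  expect_error(scenario(cylinder_tau = -1), "cylinder_tau")
  expect_error(scenario(setpoint_profile = 130), "\\[0, 100\\]")
  expect_error(scenario(duration = 1e-4, dt = 1e-3), "duration")
  expect_error(scenario(controller = list(type = "lqr")), "controller")
  expect_error(scenario(noise = list(std = 1)), "seed")
  sc <- scenario(setpoint_profile = data.frame(time = c(0, 10),
                                               value = c(95, 80)))
  expect_s3_class(sc, "scenario")
})

test_that("the open-loop infected plant settles at its DC gain, below the commanded level", {
  sc <- scenario_library()$open_loop_step
  sc$duration <- 40
  res <- run_scenario(sc)
  y_end <- tail(res$trajectories$y, 1)
  expect_equal(y_end, 95 * 62 / 67, tolerance = 1e-2)
  expect_lt(max(res$trajectories$y), 95)
})

test_that("the engine is bit-deterministic without noise and seed-reproducible with it", {
  sc <- scenario(name = "det", duration = 4, controller = list(type = "pid"))
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1$trajectories, r2$trajectories)
  scn <- scenario(name = "noisy", duration = 4,
                  controller = list(type = "pid"),
                  noise = list(std = 0.5, seed = 42))
  n1 <- run_scenario(scn)
  n2 <- run_scenario(scn)
  expect_identical(n1$trajectories, n2$trajectories)
  expect_false(identical(n1$trajectories$y, r1$trajectories$y))
})

test_that("piecewise set-point profiles are honoured", {
  sc <- scenario(name = "steps",
                 setpoint_profile = data.frame(time = c(0, 2),
                                               value = c(50, 70)),
                 duration = 4, controller = list(type = "none"))
  res <- run_scenario(sc)
  tr <- res$trajectories
  expect_true(all(tr$r[tr$t < 2] == 50))
  expect_true(all(tr$r[tr$t >= 2] == 70))
})

test_that("metrics match closed forms on a synthetic first-order response", {
  dt <- 1e-3
  t <- seq(0, 60, by = dt)
  tau <- 3
  y <- 95 * (1 - exp(-t / tau))
  m <- compute_metrics(fake_result(t, y, rep(95, length(t)), dt))
  expect_equal(m$overshoot_pct, 0)
  expect_equal(m$settling_time_s, tau * log(1 / 0.02), tolerance = 0.01)
  expect_equal(m$rise_time_s, tau * (log(10) - log(10 / 9)), tolerance = 0.01)
  # perfect tracking: all zero
  mz <- compute_metrics(fake_result(t, rep(95, length(t)),
                                    rep(95, length(t)), dt))
  expect_equal(mz$overshoot_pct, 0)
  expect_equal(mz$settling_time_s, 0)
  expect_equal(mz$iae, 0)
  # never settles within the horizon: flagged NaN
  mo <- compute_metrics(fake_result(t, rep(80, length(t)),
                                    rep(95, length(t)), dt))
  expect_false(mo$settled)
  expect_true(is.nan(mo$settling_time_s))
})

test_that("the scenario library is complete and serializes faithfully", {
  lib <- scenario_library()
  expect_setequal(names(lib),
                  c("open_loop_step", "cylinder_tau_sweep",
                    "mrac_gamma_sweep", "tracking_95", "tracking_90",
                    "pid_95", "gas_model_variants", "input_delay_sweep",
                    "setpoint_load_event", "exchange_delay_sweep"))
  expect_true(0.5 %in% lib$cylinder_tau_sweep$sweep$values)
  expect_setequal(lib$gas_model_variants$sweep$values,
                  c("model1", "model2", "model3"))
  expect_equal(lib$exchange_delay_sweep$sweep$values, c(0.3, 0.5, 0.7))
  for (nm in names(lib)) {
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_scenario_yaml(lib[[nm]], tmp)
    expect_equal(load_scenario_yaml(tmp), lib[[nm]], label = nm)
  }
})

test_that("run_sweep substitutes plant and controller parameters", {
  sc <- scenario(name = "s", duration = 2, controller = list(type = "mrac"))
  sc$sweep <- list(param = "controller.gamma", values = c(1e-5, 2e-5))
  res <- run_sweep(sc)
  expect_named(res, c("controller.gamma=1e-05", "controller.gamma=2e-05"))
  expect_equal(res[[1]]$scenario$controller$gamma, 1e-5)
  sc2 <- scenario(name = "s2", duration = 2)
  sc2$sweep <- list(param = "intermediate_delay", values = c(0, 0.1))
  res2 <- run_sweep(sc2)
  expect_equal(res2[[2]]$scenario$intermediate_delay, 0.1)
})

test_that("halving the step leaves the closed-loop steady state unchanged", {
  sc <- scenario_library()$tracking_95
  sc$duration <- 30
  res1 <- run_scenario(sc)
  sc$dt <- 5e-4
  res2 <- run_scenario(sc)
  f1 <- compute_metrics(res1)$final_5s_mean
  f2 <- compute_metrics(res2)$final_5s_mean
  expect_lt(abs(f1 - f2) / f1, 1e-3)
})
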