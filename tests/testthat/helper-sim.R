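# Fabricate a simulation_result from explicit trajectories, for metric
# oracle tests that need a known analytic response.
fake_result <- function(t, y, r, dt = t[2] - t[1]) {
  n <- length(t)
  sc <- scenario(name = "synthetic", setpoint_profile = r[1],
                 duration = max(t), dt = dt)
  tr <- data.frame(t = t, r = r, r_mod = r, u = 0, y = y, ym = y,
                   e = 0, theta = NA_real_, m = NA_real_)
  structure(list(scenario = sc, trajectories = tr),
            class = "simulation_result")
}

# Step one discretized block n times with a constant input, returning the
# final output sample.
step_constant <- function(blk, u, n) {
  y <- NA_real_
  for (i in seq_len(n)) {
    s <- block_step(blk, u)
    blk <- s$blk
    y <- s$y
  }
  y
}

# Closed-loop MIT-rule adaptation on the matched first-order toy pair
# (plant K/(s+1), reference K0/(s+1)) with the package's fixed-step blocks.
mit_toy_fixed_step <- function(K = 2, K0 = 1, gamma = 0.5, r = 1,
                               duration = 150, dt = 1e-3) {
  plant <- discretize(rtf(K, c(1, 1)), dt)
  ref <- discretize(rtf(K0, c(1, 1)), dt)
  state <- list(theta = 0, gamma = gamma)
  y <- 0; ym <- 0
  n <- round(duration / dt)
  for (k in seq_len(n)) {
    state <- mit_update(state, y - ym, ym, dt)
    s <- block_step(plant, r * state$theta); plant <- s$blk; y <- s$y
    s <- block_step(ref, r); ref <- s$blk; ym <- s$y
  }
  state$theta
}
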