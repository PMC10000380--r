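#' Closed-loop simulation scenario
#'
#' Full description of one experiment: set-point profile, plant
#' configuration (oxygen-source time constant, airway condition,
#' gas-exchange variant, transport delays), controller configuration,
#' horizon and step. Scenarios are plain, YAML-serializable descriptions;
#' [run_scenario()] executes them.
#'
#' @param name Scenario name (used in output file naming).
#' @param setpoint_profile Data frame with columns `time`, `value`:
#'   piecewise-constant commanded SpO2, % (value i holds from time i until
#'   the next breakpoint). A single number is shorthand for a constant
#'   set-point from t = 0.
#' @param cylinder_tau Oxygen-source time constant, s.
#' @param condition `"infected"` or `"healthy"` airway cascade.
#' @param input_delay Transport delay between controller/source and the
#'   airway, s.
#' @param intermediate_delay Transport delay between the airway cascade and
#'   the gas-exchange block, s.
#' @param gas_model_variant `"canonical"`, `"model1"`, `"model2"`,
#'   `"model3"`.
#' @param controller Controller configuration: list with `type` in
#'   `"sfpimrac"`, `"mrac"`, `"pid"`, `"none"` plus the fields of the
#'   matching constructor (e.g. `gamma` for mrac; `G_e`, `G_de`, `theta0`,
#'   `u_max` for sfpimrac). `"none"` applies the commanded set-point
#'   directly as the plant input (open loop).
#' @param duration Horizon, s.
#' @param dt Fixed step, s (default 1 ms; delays are rounded to whole
#'   samples).
#' @param noise Optional measurement noise: list with `std` (% SpO2) and
#'   `seed` (mandatory when `std > 0`); the only source of randomness.
#' @param reference_drive `"command"` (default) drives the reference model
#'   with r, so the target trajectory is fixed; `"modulated"` drives it
#'   with r'.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = "custom",
                     setpoint_profile = 95,
                     cylinder_tau = 0.5,
                     condition = c("infected", "healthy"),
                     input_delay = 0,
                     intermediate_delay = 0,
                     gas_model_variant = c("canonical", "model1", "model2",
                                           "model3"),
                     controller = list(type = "sfpimrac"),
                     duration = 60,
                     dt = 1e-3,
                     noise = NULL,
                     reference_drive = c("command", "modulated")) {
  condition <- match.arg(condition)
  gas_model_variant <- match.arg(gas_model_variant)
  reference_drive <- match.arg(reference_drive)
  if (is.numeric(setpoint_profile) && is.null(dim(setpoint_profile))) {
    if (length(setpoint_profile) != 1)
      stop("a numeric setpoint_profile must be a single value")
    setpoint_profile <- data.frame(time = 0, value = setpoint_profile)
  }
  if (!is.data.frame(setpoint_profile) ||
      !all(c("time", "value") %in% names(setpoint_profile)))
    stop("setpoint_profile must be a data frame with columns time, value")
  sp <- setpoint_profile[order(setpoint_profile$time),
                         c("time", "value"), drop = FALSE]
  if (sp$time[1] > 0) stop("setpoint_profile must start at time 0")
  if (any(sp$value < 0 | sp$value > 100))
    stop("set-point values must lie in [0, 100] % SpO2")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (!is.numeric(duration) || duration <= dt)
    stop("duration must exceed dt")
  for (v in list(cylinder_tau = cylinder_tau))
    if (!is.numeric(v) || v <= 0) stop("cylinder_tau must be positive")
  for (v in list(input_delay = input_delay,
                 intermediate_delay = intermediate_delay))
    if (!is.numeric(v) || v < 0) stop("delays must be >= 0")
  if (is.null(controller$type) ||
      !controller$type %in% c("sfpimrac", "mrac", "pid", "none"))
    stop("controller$type must be one of sfpimrac, mrac, pid, none")
  if (!is.null(noise)) {
    if (is.null(noise$std) || noise$std < 0)
      stop("noise$std must be >= 0")
    if (noise$std > 0 && is.null(noise$seed))
      stop("noise$seed is mandatory when noise$std > 0")
  }
  structure(list(name = name, setpoint_profile = sp,
                 cylinder_tau = cylinder_tau, condition = condition,
                 input_delay = input_delay,
                 intermediate_delay = intermediate_delay,
                 gas_model_variant = gas_model_variant,
                 controller = controller, duration = duration, dt = dt,
                 noise = noise, reference_drive = reference_drive),
            class = "scenario")
}

make_controller <- function(cfg) {
  args <- cfg[setdiff(names(cfg), "type")]
  switch(cfg$type,
    sfpimrac = do.call(sfpimrac_controller, args),
    mrac = do.call(mrac_controller, args),
    pid = do.call(pid_controller, args),
    none = structure(list(), class = "open_loop_controller"),
    stop("unknown controller type '", cfg$type, "'"))
}

#' @export
controller_init.open_loop_controller <- function(ctrl) list()

setpoint_at <- function(sp, t) {
  sp$value[findInterval(t, sp$time)]
}

#' Run a closed-loop scenario
#'
#' Fixed-step explicit loop with zero-order hold between controller and
#' plant. Per step: read the (optionally noisy) patient output, take one
#' controller step to get u, pass u through the oxygen-source lag, the
#' input delay, the four airway sections, the intermediate delay, and the
#' gas-exchange block to produce the next output; the reference model runs
#' in parallel, driven by the commanded set-point. All blocks are exact
#' ZOH discretizations; delays are exact sample shifts; with zero noise
#' the engine is bit-deterministic.
#'
#' @param sc A [scenario()].
#' @return An object of class `simulation_result`: list with the scenario
#'   and a data frame `trajectories` with columns
#'   `t, r, r_mod, u, y, ym, e, theta, m` sampled at every step.
#' @export
run_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  dt <- sc$dt
  nstep <- as.integer(round(sc$duration / dt))
  airway <- airway_cascade(sc$condition)
  gas <- gas_exchange_tf(sc$gas_model_variant)
  cyl <- discretize(cylinder_tf(sc$cylinder_tau), dt)
  segs <- list(discretize(segment_tf("nasal"), dt),
               discretize(segment_tf("trachea"), dt),
               discretize(segment_tf("bronchi"), dt),
               discretize(if (sc$condition == "infected")
                 infected_alveoli_tf() else segment_tf("alveoli"), dt))
  gasblk <- discretize(gas, dt)
  refblk <- discretize(reference_model_tf(), dt)
  dl_in <- delay_line(sc$input_delay, dt)
  dl_mid <- delay_line(sc$intermediate_delay, dt)
  ctrl <- make_controller(sc$controller)
  cstate <- controller_init(ctrl)
  open_loop <- inherits(ctrl, "open_loop_controller")

  noise <- if (!is.null(sc$noise) && sc$noise$std > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(sc$noise$seed)
    stats::rnorm(nstep, 0, sc$noise$std)
  } else NULL

  tgrid <- seq(0, by = dt, length.out = nstep + 1L)
  rvec <- setpoint_at(sc$setpoint_profile, tgrid)
  out <- matrix(NA_real_, nstep + 1L, 8L)
  colnames(out) <- c("r_mod", "u", "y", "ym", "e", "theta", "m", "ymeas")
  y <- 0; ym <- 0
  out[1, ] <- c(rvec[1], 0, 0, 0, 0,
                if (is.null(cstate$theta)) NA_real_ else cstate$theta,
                if (is.null(cstate$m)) NA_real_ else cstate$m, 0)
  for (k in seq_len(nstep)) {
    r <- rvec[k]
    ymeas <- if (is.null(noise)) y else y + noise[k]
    # reference model (driven by the command by default)
    ref_in <- r
    if (open_loop) {
      u <- r; r_mod <- r; theta <- NA_real_; m <- NA_real_
    } else {
      st <- switch(class(ctrl)[1],
        sfpimrac_controller = sfpimrac_step(ctrl, cstate, r, ymeas, ym, dt),
        mrac_controller = mrac_step(ctrl, cstate, r, ymeas, ym, dt),
        pid_controller = pid_step(ctrl, cstate, r, ymeas, ym, dt))
      cstate <- st$state
      u <- st$outputs$u; r_mod <- st$outputs$r_mod
      theta <- st$outputs$theta; m <- st$outputs$m
      if (inherits(ctrl, "sfpimrac_controller") &&
          sc$reference_drive == "modulated") ref_in <- r_mod
    }
    s <- block_step(refblk, ref_in); refblk <- s$blk; ym <- s$y
    s <- block_step(cyl, u); cyl <- s$blk; v <- s$y
    s <- delay_step(dl_in, v); dl_in <- s$dl; v <- s$y
    for (i in 1:4) { s <- block_step(segs[[i]], v); segs[[i]] <- s$blk; v <- s$y }
    s <- delay_step(dl_mid, v); dl_mid <- s$dl; v <- s$y
    s <- block_step(gasblk, v); gasblk <- s$blk; y <- s$y
    if (!is.finite(y) || !is.finite(ym))
      stop("non-finite state at step ", k, " (t = ", k * dt, " s)")
    out[k + 1L, ] <- c(r_mod, u, y, ym, y - ym, theta, m, ymeas)
  }
  traj <- data.frame(t = tgrid, r = rvec, r_mod = out[, "r_mod"],
                     u = out[, "u"], y = out[, "y"], ym = out[, "ym"],
                     e = out[, "e"], theta = out[, "theta"],
                     m = out[, "m"])
  structure(list(scenario = sc, trajectories = traj),
            class = "simulation_result")
}

#' Tracking-performance metrics of a simulation result
#'
#' Operational versions of the usual step-response criteria, measured
#' against the final commanded set-point `r_final`:
#' * `overshoot_pct`: `max(y - r_final)/r_final * 100`, clipped at 0;
#' * `settling_time_s`: first time after which `|y - r_final|` stays
#'   within `band * r_final` for the rest of the horizon (`NaN`, flagged,
#'   if never);
#' * `rise_time_s`: time from 10% to 90% of `r_final` (first crossings);
#' * `steady_state_error`: `|mean(y over the final 5 s) - r_final|`;
#' * `iae`: integral of `|r(t) - y(t)| dt` over the horizon.
#'
#' @param res A `simulation_result`.
#' @param band Settling band as a fraction of `r_final` (default 0.02).
#' @return An object of class `performance_metrics` (a list), with a
#'   logical `settled` flag.
#' @export
compute_metrics <- function(res, band = 0.02) {
  stopifnot(inherits(res, "simulation_result"))
  tr <- res$trajectories
  t <- tr$t; y <- tr$y; r <- tr$r
  r_final <- r[length(r)]
  overshoot <- max(0, (max(y) - r_final) / r_final * 100)
  tol <- band * r_final
  outside <- abs(y - r_final) > tol
  if (!outside[length(outside)] && any(!outside)) {
    last_out <- if (any(outside)) max(which(outside)) else 0L
    settling <- if (last_out == 0L) 0 else t[last_out + 1L]
    settled <- TRUE
  } else {
    settling <- NaN
    settled <- FALSE
  }
  i10 <- which(y >= 0.1 * r_final)
  i90 <- which(y >= 0.9 * r_final)
  rise <- if (length(i10) && length(i90)) t[i90[1]] - t[i10[1]] else NaN
  win <- t >= max(t) - 5
  sse <- abs(mean(y[win]) - r_final)
  dt <- res$scenario$dt
  iae <- sum(abs(r - y)) * dt
  structure(list(overshoot_pct = overshoot, settling_time_s = settling,
                 settled = settled, rise_time_s = rise,
                 steady_state_error = sse, iae = iae,
                 final_5s_mean = mean(y[win]), r_final = r_final,
                 band = band),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("overshoot: %.3f %%  settling (%.0f%% band): %s s  rise: %s s\n",
              x$overshoot_pct, 100 * x$band,
              if (x$settled) sprintf("%.2f", x$settling_time_s) else "not settled",
              if (is.nan(x$rise_time_s)) "NA" else sprintf("%.2f", x$rise_time_s)))
  cat(sprintf("steady-state error: %.4f  IAE: %.2f  final-5s mean: %.3f\n",
              x$steady_state_error, x$iae, x$final_5s_mean))
  invisible(x)
}

#' Library of reproducible study scenarios
#'
#' Named, fully specified scenarios covering the closed-loop studies this
#' package reproduces. Entries whose study is a parameter sweep carry a
#' `sweep` field (`param`, `values`); [run_sweep()] executes them. Every
#' value the underlying studies leave unstated (horizons, sweep grids,
#' PID gains) is a documented default here (see the methods vignette).
#'
#' * `open_loop_step`: infected plant, no controller, command 95 — the
#'   output settles at DC gain x 95 < 95, motivating closed-loop control.
#' * `cylinder_tau_sweep`: SFPIMRAC with source time constants
#'   {0.25, 0.50, 1.0} s (0.50 s is the study default).
#' * `mrac_gamma_sweep`: plain MRAC with adaptation gains
#'   {5e-5, 1e-4, 2e-4}, 120 s horizon.
#' * `tracking_95`, `tracking_90`: SFPIMRAC at the two studied set-points.
#' * `pid_95`: hand-tuned PID baseline at 95.
#' * `gas_model_variants`: SFPIMRAC against gas-exchange variants
#'   model1-3.
#' * `input_delay_sweep`: input transport delays {0.30, 0.50, 0.70} s.
#' * `setpoint_load_event`: command 95, dropped to 80 for 20 s, back to
#'   95, with a 0.30 s input delay, 120 s horizon.
#' * `exchange_delay_sweep`: intermediate (gas-transport) delays
#'   {0.30, 0.50, 0.70} s.
#'
#' @return Named list of [scenario()] objects.
#' @export
scenario_library <- function() {
  sf <- list(type = "sfpimrac")
  lib <- list(
    open_loop_step = scenario("open_loop_step",
                              controller = list(type = "none"),
                              duration = 60),
    cylinder_tau_sweep = scenario("cylinder_tau_sweep", controller = sf,
                                  duration = 60),
    mrac_gamma_sweep = scenario("mrac_gamma_sweep",
                                controller = list(type = "mrac",
                                                  gamma = 1e-4),
                                duration = 120),
    tracking_95 = scenario("tracking_95", 95, controller = sf,
                           duration = 60),
    tracking_90 = scenario("tracking_90", 90, controller = sf,
                           duration = 60),
    pid_95 = scenario("pid_95", 95, controller = list(type = "pid"),
                      duration = 60),
    gas_model_variants = scenario("gas_model_variants", controller = sf,
                                  duration = 60),
    input_delay_sweep = scenario("input_delay_sweep", controller = sf,
                                 duration = 60),
    setpoint_load_event = scenario(
      "setpoint_load_event",
      setpoint_profile = data.frame(time = c(0, 40, 60),
                                    value = c(95, 80, 95)),
      controller = sf, input_delay = 0.3, duration = 120),
    exchange_delay_sweep = scenario("exchange_delay_sweep", controller = sf,
                                    duration = 60))
  lib$cylinder_tau_sweep$sweep <- list(param = "cylinder_tau",
                                       values = c(0.25, 0.5, 1.0))
  lib$mrac_gamma_sweep$sweep <- list(param = "controller.gamma",
                                     values = c(5e-5, 1e-4, 2e-4))
  lib$gas_model_variants$sweep <- list(param = "gas_model_variant",
                                       values = c("model1", "model2",
                                                  "model3"))
  lib$input_delay_sweep$sweep <- list(param = "input_delay",
                                      values = c(0.3, 0.5, 0.7))
  lib$exchange_delay_sweep$sweep <- list(param = "intermediate_delay",
                                         values = c(0.3, 0.5, 0.7))
  lib
}

#' Run a sweep scenario
#'
#' Executes a scenario once per sweep value, substituting the swept
#' parameter (dotted names index into the controller config).
#'
#' @param sc A [scenario()] carrying a `sweep` field, or a plain scenario
#'   (run once).
#' @return Named list of `simulation_result`s.
#' @export
run_sweep <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (is.null(sc$sweep)) {
    res <- list(run_scenario(sc))
    names(res) <- sc$name
    return(res)
  }
  param <- sc$sweep$param
  out <- list()
  for (v in sc$sweep$values) {
    sci <- sc
    sci$sweep <- NULL
    if (startsWith(param, "controller.")) {
      sci$controller[[sub("^controller\\.", "", param)]] <- v
    } else {
      sci[[param]] <- v
    }
    sci$name <- paste0(sc$name, "_", v)
    out[[paste0(param, "=", v)]] <- run_scenario(sci)
  }
  out
}
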