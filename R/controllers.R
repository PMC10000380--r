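#' MIT-rule parameter update (plain MRAC)
#'
#' One explicit-Euler step of the gradient adaptation law
#' \deqn{\frac{d\theta}{dt} = -\gamma\, y_m\, e,}
#' which descends the squared model-following error \eqn{F(\theta) = e^2/2}
#' for sufficiently small adaptation gain on matched plants. `e = y - ym`
#' is the model-following error and `ym` the reference-model output.
#'
#' @param state List with at least `theta` (adjustable parameter) and
#'   `gamma` (adaptation gain > 0).
#' @param e Model-following error y - ym.
#' @param ym Reference-model output.
#' @param dt Time step, s (> 0).
#' @return The updated state.
#' @export
mit_update <- function(state, e, ym, dt) {
  if (!is.finite(e) || !is.finite(ym)) stop("e and ym must be finite")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (is.null(state$gamma) || !is.finite(state$gamma) || state$gamma <= 0)
    stop("state$gamma must be a positive number")
  if (!is.finite(state$theta)) stop("state$theta must be finite")
  state$theta <- state$theta - state$gamma * ym * e * dt
  state
}

#' Fuzzy-adapted parameter update
#'
#' The fuzzy analog of the MIT rule: the product \eqn{\gamma\, e} of the
#' gradient law is replaced by the inferred gain \eqn{m(e, \Delta e)}, and
#' the reference output enters as a fraction of the SpO2 scale:
#' \deqn{\frac{d\theta}{dt} = -m(e, \Delta e)\; \frac{y_m}{y_{scale}}.}
#' At `e = de = 0` the inferred gain is 0 and theta holds ("maintain the
#' same flow"). Normalizing \eqn{y_m} by the output scale (default 100, the
#' % SpO2 span) bounds the theta slew rate at ~1/s even when m saturates;
#' without it a saturated gain would slew theta at ~100/s and the loop
#' limit-cycles (see the methods vignette).
#'
#' The memoryless reading of the published law, \eqn{\theta = -m\, y_m}
#' applied directly rather than integrated, is available via
#' `literal = TRUE` for comparison; it cannot track (it forces u = 0
#' whenever e = 0) and is not used by the shipped scenarios.
#'
#' @param state List with `theta` and `e_prev`.
#' @param e Model-following error y - ym, % SpO2.
#' @param de Error rate, %/s.
#' @param ym Reference-model output, % SpO2.
#' @param sys A [fuzzy_gain_system()].
#' @param dt Time step, s (> 0).
#' @param y_scale Output scale dividing ym in the integrand; default 100.
#' @param literal If `TRUE`, apply the memoryless law instead of
#'   integrating.
#' @return The updated state (also carries the inferred `m`).
#' @export
fuzzy_adaptive_update <- function(state, e, de, ym, sys, dt,
                                  y_scale = 100, literal = FALSE) {
  if (!is.finite(e) || !is.finite(de) || !is.finite(ym))
    stop("e, de and ym must be finite")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  m <- infer_gain(e, de, sys)
  if (literal) {
    state$theta <- -m * ym
  } else {
    state$theta <- state$theta - m * (ym / y_scale) * dt
  }
  state$m <- m
  state
}

#' Set-point modulation
#'
#' Temporary inflation/deflation of the commanded set-point by the current
#' tracking error: \eqn{r' = r + (r - y)}, clipped to `[0, 100]` % SpO2.
#' At y = r the modulation vanishes (r' = r), during undershoot r' > r
#' boosts the drive, during overshoot r' < r backs it off; the steady-state
#' target is unchanged.
#'
#' @param r Commanded set-point, % SpO2 (in `[0, 100]`).
#' @param y Patient output (pulse-oximeter reading), % SpO2.
#' @return The dynamic set-point r' in `[0, 100]`.
#' @examples
#' modulate_setpoint(95, 80)  # deep undershoot -> clipped at 100
#' modulate_setpoint(95, 97)  # overshoot -> 93
#' @export
modulate_setpoint <- function(r, y) {
  if (!is.finite(r) || !is.finite(y)) stop("r and y must be finite")
  if (r < 0 || r > 100) stop("r must lie in [0, 100] % SpO2")
  min(max(r + (r - y), 0), 100)
}

#' SFPIMRAC controller configuration
#'
#' The set-point-modulated fuzzy-PI model-reference adaptive controller:
#' fuzzy inference supplies the adaptation gain, the adjustable parameter
#' theta is integrated by [fuzzy_adaptive_update()], and the control signal
#' is the product of theta with the modulated set-point,
#' \eqn{u = r' \theta}, clamped to `[0, u_max]` (an oxygen supply cannot be
#' negative).
#'
#' Defaults: `G_e = 1` (the error in % SpO2 maps directly onto the
#' `[-100, 100]` universe) and `G_de = 5` (derivative lead that damps the
#' delayed loop; see the methods vignette for the loop-gain rationale).
#'
#' @param sys A [fuzzy_gain_system()].
#' @param G_e,G_de Input scaling gains applied to e and de before
#'   inference.
#' @param theta0 Initial adjustable parameter.
#' @param u_max Control clamp, % of full supply scale.
#' @param y_scale Output scale for the adaptation integrand.
#' @param modulate If `FALSE`, the raw set-point drives u (ablation switch).
#' @param literal Use the memoryless theta law (see
#'   [fuzzy_adaptive_update()]).
#' @return An object of class `sfpimrac_controller`.
#' @export
sfpimrac_controller <- function(sys = fuzzy_gain_system(), G_e = 1,
                                G_de = 5, theta0 = 0, u_max = 200,
                                y_scale = 100, modulate = TRUE,
                                literal = FALSE) {
  stopifnot(inherits(sys, "fuzzy_gain_system"))
  for (v in list(G_e = G_e, G_de = G_de, u_max = u_max, y_scale = y_scale))
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("G_e, G_de, u_max and y_scale must be positive numbers")
  structure(list(sys = sys, G_e = G_e, G_de = G_de, theta0 = theta0,
                 u_max = u_max, y_scale = y_scale, modulate = modulate,
                 literal = literal),
            class = "sfpimrac_controller")
}

#' Initial controller state
#'
#' @param ctrl A controller configuration.
#' @return A list holding the controller's mutable state.
#' @export
controller_init <- function(ctrl) UseMethod("controller_init")

#' @export
controller_init.sfpimrac_controller <- function(ctrl) {
  list(theta = ctrl$theta0, e_prev = 0, m = 0)
}

#' One SFPIMRAC step
#'
#' Computes `e = y - ym` and its backward difference, updates theta by
#' [fuzzy_adaptive_update()], modulates the set-point, and returns
#' `u = r' theta` clamped to `[0, u_max]`.
#'
#' @param ctrl An [sfpimrac_controller()].
#' @param state Controller state from [controller_init()].
#' @param r Commanded set-point, % SpO2.
#' @param y Measured patient output, % SpO2.
#' @param ym Reference-model output, % SpO2.
#' @param dt Time step, s.
#' @return List with `outputs` (list `u`, `r_mod`, `m`, `theta`) and the
#'   updated `state`.
#' @export
sfpimrac_step <- function(ctrl, state, r, y, ym, dt) {
  stopifnot(inherits(ctrl, "sfpimrac_controller"))
  if (!is.finite(r) || !is.finite(y) || !is.finite(ym))
    stop("r, y and ym must be finite")
  e <- y - ym
  de <- (e - state$e_prev) / dt
  state <- fuzzy_adaptive_update(state, ctrl$G_e * e, ctrl$G_de * de, ym,
                                 ctrl$sys, dt, y_scale = ctrl$y_scale,
                                 literal = ctrl$literal)
  state$e_prev <- e
  r_mod <- if (ctrl$modulate) modulate_setpoint(r, y) else r
  u <- min(max(r_mod * state$theta, 0), ctrl$u_max)
  list(outputs = list(u = u, r_mod = r_mod, m = state$m,
                      theta = state$theta),
       state = state)
}

#' Plain MRAC controller configuration
#'
#' MIT-rule model-reference adaptive control with fixed adaptation gain
#' gamma and control law `u = r theta` clamped to `[0, u_max]`.
#'
#' @param gamma Adaptation gain (> 0).
#' @param theta0 Initial adjustable parameter.
#' @param u_max Control clamp.
#' @return An object of class `mrac_controller`.
#' @export
mrac_controller <- function(gamma = 1e-4, theta0 = 0, u_max = 200) {
  if (!is.numeric(gamma) || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a positive number")
  structure(list(gamma = gamma, theta0 = theta0, u_max = u_max),
            class = "mrac_controller")
}

#' @export
controller_init.mrac_controller <- function(ctrl) {
  list(theta = ctrl$theta0, gamma = ctrl$gamma)
}

#' One MRAC step
#'
#' @inheritParams sfpimrac_step
#' @param ctrl An [mrac_controller()].
#' @return As [sfpimrac_step()]; `r_mod` equals `r` and `m` is `NA` (no
#'   fuzzy stage).
#' @export
mrac_step <- function(ctrl, state, r, y, ym, dt) {
  stopifnot(inherits(ctrl, "mrac_controller"))
  state <- mit_update(state, y - ym, ym, dt)
  u <- min(max(r * state$theta, 0), ctrl$u_max)
  list(outputs = list(u = u, r_mod = r, m = NA_real_,
                      theta = state$theta),
       state = state)
}

#' PID controller configuration (baseline)
#'
#' Textbook parallel PID on the set-point error `r - y` with clamping
#' anti-windup: the integrator is frozen whenever the unclamped output
#' exceeds the limits in the direction that would deepen saturation. The
#' default gains are a documented hand-tuning on the composite patient
#' model (see the methods vignette); they give a visibly overshooting but
#' settling baseline.
#'
#' @param kp,ki,kd Proportional/integral/derivative gains (>= 0).
#' @param u_min,u_max Output limits.
#' @return An object of class `pid_controller`.
#' @export
pid_controller <- function(kp = 1, ki = 0.3, kd = 0, u_min = 0,
                           u_max = 200) {
  for (v in list(kp = kp, ki = ki, kd = kd))
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      stop("PID gains must be numbers >= 0")
  if (u_min >= u_max) stop("u_min must be < u_max")
  structure(list(kp = kp, ki = ki, kd = kd, u_min = u_min, u_max = u_max),
            class = "pid_controller")
}

#' @export
controller_init.pid_controller <- function(ctrl) {
  list(integral = 0, e_prev = 0, first = TRUE)
}

#' One PID step
#'
#' @inheritParams sfpimrac_step
#' @param ctrl A [pid_controller()].
#' @return As [sfpimrac_step()]; `theta` and `m` are `NA`.
#' @export
pid_step <- function(ctrl, state, r, y, ym, dt) {
  stopifnot(inherits(ctrl, "pid_controller"))
  err <- r - y
  d <- if (state$first) 0 else (err - state$e_prev) / dt
  state$first <- FALSE
  integral_cand <- state$integral + err * dt
  u_raw <- ctrl$kp * err + ctrl$ki * integral_cand + ctrl$kd * d
  if ((u_raw > ctrl$u_max && err > 0) || (u_raw < ctrl$u_min && err < 0)) {
    # saturating further: freeze the integrator
    u_raw <- ctrl$kp * err + ctrl$ki * state$integral + ctrl$kd * d
  } else {
    state$integral <- integral_cand
  }
  state$e_prev <- err
  u <- min(max(u_raw, ctrl$u_min), ctrl$u_max)
  list(outputs = list(u = u, r_mod = r, m = NA_real_, theta = NA_real_),
       state = state)
}
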