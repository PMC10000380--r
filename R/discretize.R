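#' Exact zero-order-hold discretization of a transfer function
#'
#' Realizes the delay-free part of an `rtf` in controllable canonical
#' state-space form and discretizes it exactly under a zero-order hold via
#' the augmented matrix exponential
#' \eqn{\exp\left(\begin{smallmatrix}A & B\\ 0 & 0\end{smallmatrix}\right) dt}.
#' Stepping the result with a constant input converges to DC-gain x input.
#' The block's dead time is *not* realized here (use [delay_line()]); the
#' simulator composes the two so that delays stay exact sample shifts.
#'
#' @param tf A strictly proper or biproper `rtf`. Biproper numerators are
#'   split off as a direct feedthrough term.
#' @param dt Sampling step, s (> 0).
#' @return An object of class `ss_block`: list with `Ad`, `Bd`, `C`, `D`,
#'   state vector `x` (initially 0), and `dt`.
#' @examples
#' blk <- discretize(cylinder_tf(0.5), 0.001)
#' @export
discretize <- function(tf, dt) {
  stopifnot(is_rtf(tf))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  den <- tf$den / tf$den[1]
  num <- tf$num / tf$den[1]
  n <- length(den) - 1L
  if (n == 0) {
    return(structure(list(Ad = matrix(0, 0, 0), Bd = numeric(0),
                          C = numeric(0), D = num, x = numeric(0), dt = dt),
                     class = "ss_block"))
  }
  D <- 0
  if (length(num) == length(den)) {      # biproper: split feedthrough
    D <- num[1]
    num <- drop_leading_zeros(num - D * den)
    if (identical(num, 0)) num <- numeric(0)
  }
  b <- rev(num)
  b <- c(b, rep(0, n - length(b)))
  a <- rev(den[-1])
  A <- matrix(0, n, n)
  if (n > 1) A[cbind(1:(n - 1), 2:n)] <- 1
  A[n, ] <- -a
  B <- c(rep(0, n - 1), 1)
  M <- rbind(cbind(A, B), rep(0, n + 1)) * dt
  E <- as.matrix(Matrix::expm(M))
  Ad <- E[1:n, 1:n, drop = FALSE]
  Bd <- E[1:n, n + 1]
  # a stable continuous pole must map inside the unit circle
  cp <- polyroot(rev(den))
  zp <- eigen(Ad, only.values = TRUE)$values
  if (all(Re(cp) < 0) && any(Mod(zp) >= 1))
    stop("discretization produced an unstable pole from a stable ",
         "continuous-time model; dt is too large for this block")
  structure(list(Ad = Ad, Bd = Bd, C = b, D = D, x = rep(0, n), dt = dt),
            class = "ss_block")
}

#' Advance a discretized block one sample
#'
#' @param blk An `ss_block` from [discretize()].
#' @param u Scalar input sample.
#' @return List with the updated `blk` and the output sample `y`.
#' @export
block_step <- function(blk, u) {
  if (length(blk$x)) {
    y <- sum(blk$C * blk$x) + blk$D * u
    blk$x <- drop(blk$Ad %*% blk$x) + blk$Bd * u
  } else {
    y <- blk$D * u
  }
  list(blk = blk, y = y)
}

#' Pure transport-delay line
#'
#' Delays its input by `round(d/dt)` whole samples (zero-padded before
#' `t = d`). Rounding to the nearest sample is reported in the returned
#' object so callers can log it. Composing two delay lines equals one line
#' with the summed delay.
#'
#' @param d Delay, s (>= 0).
#' @param dt Sampling step, s (> 0).
#' @return An object of class `delay_line`: list with `n` (samples),
#'   `d_requested`, `d_actual`, and ring buffer state.
#' @export
delay_line <- function(d, dt) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d < 0)
    stop("delay must be a single number >= 0")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  n <- as.integer(round(d / dt))
  structure(list(n = n, d_requested = d, d_actual = n * dt,
                 buf = if (n > 0) numeric(n) else numeric(0), pos = 1L),
            class = "delay_line")
}

#' Advance a delay line one sample
#'
#' @param dl A [delay_line()].
#' @param u Scalar input sample.
#' @return List with the updated `dl` and the delayed output sample `y`.
#' @export
delay_step <- function(dl, u) {
  if (dl$n == 0L) return(list(dl = dl, y = u))
  y <- dl$buf[dl$pos]
  dl$buf[dl$pos] <- u
  dl$pos <- if (dl$pos == dl$n) 1L else dl$pos + 1L
  list(dl = dl, y = y)
}
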