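#' Rational transfer function with optional dead time
#'
#' Continuous-time proper rational transfer function
#' \eqn{H(s) = e^{-s d}\, N(s)/D(s)}, the common currency of the plant
#' blocks in this package. Coefficients are stored in descending powers of
#' \eqn{s}, in the order one writes them by hand.
#'
#' @param num Numeric vector of numerator coefficients, descending powers.
#' @param den Numeric vector of denominator coefficients, descending powers.
#' @param dead_time Transport delay in seconds (>= 0). The delay is kept
#'   symbolic here: it is realized exactly as a sample shift in the
#'   time-domain simulator and as the phase factor \eqn{e^{-j\omega d}} in
#'   the frequency response. No Pade approximation is used anywhere.
#' @return An object of class `rtf`.
#' @examples
#' cylinder_tf(0.5)
#' rtf(1, c(1, 2.5, 1))   # the reference model used for SpO2 tracking
#' @export
rtf <- function(num, den, dead_time = 0) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (!length(num) || !length(den)) stop("num and den must be nonempty")
  if (any(!is.finite(num)) || any(!is.finite(den)))
    stop("transfer-function coefficients must be finite")
  num <- drop_leading_zeros(num)
  den <- drop_leading_zeros(den)
  if (all(den == 0)) stop("denominator is identically zero")
  if (length(num) > length(den))
    stop("improper transfer function: deg(num) > deg(den)")
  if (!is.numeric(dead_time) || length(dead_time) != 1 || !is.finite(dead_time) ||
      dead_time < 0)
    stop("dead_time must be a single finite number >= 0")
  structure(list(num = num, den = den, dead_time = dead_time), class = "rtf")
}

drop_leading_zeros <- function(p) {
  i <- which(p != 0)
  if (!length(i)) return(0)
  p[i[1]:length(p)]
}

#' @export
print.rtf <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 6), collapse = ", ")
  cat("rational transfer function (descending coefficients)\n")
  cat("  num: [", fmt(x$num), "]\n", sep = "")
  cat("  den: [", fmt(x$den), "]\n", sep = "")
  if (x$dead_time > 0) cat("  dead time:", x$dead_time, "s\n")
  invisible(x)
}

is_rtf <- function(x) inherits(x, "rtf")

#' Series (cascade) combination of transfer functions
#'
#' Multiplies transfer functions by exact polynomial convolution of the
#' coefficient arrays; dead times add. No normalization or balancing is
#' applied, so cascade coefficients can be compared literally against
#' hand-computed products.
#'
#' @param ... `rtf` objects.
#' @return The product as an `rtf`.
#' @export
tf_series <- function(...) {
  tfs <- list(...)
  stopifnot(length(tfs) >= 1, all(vapply(tfs, is_rtf, logical(1))))
  num <- 1; den <- 1; d <- 0
  for (tf in tfs) {
    num <- poly_mult(num, tf$num)
    den <- poly_mult(den, tf$den)
    d <- d + tf$dead_time
  }
  rtf(num, den, dead_time = d)
}

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

poly_eval <- function(p, s) {
  # Horner scheme, works for complex s (vectorized over s)
  acc <- rep.int(if (is.complex(s)) 0 + 0i else 0, length(s))
  for (coef in p) acc <- acc * s + coef
  acc
}

#' DC gain of a transfer function
#'
#' @param tf An `rtf`.
#' @return `num(0)/den(0)`; `Inf` for integrating systems.
#' @export
dc_gain <- function(tf) {
  stopifnot(is_rtf(tf))
  n0 <- tf$num[length(tf$num)]
  d0 <- tf$den[length(tf$den)]
  if (d0 == 0) return(Inf * sign(n0))
  n0 / d0
}

#' Poles of a transfer function
#'
#' @param tf An `rtf`.
#' @return Complex vector of denominator roots.
#' @export
tf_poles <- function(tf) {
  stopifnot(is_rtf(tf))
  if (length(tf$den) == 1) return(complex(0))
  polyroot(rev(tf$den))
}

#' Is a transfer function BIBO stable?
#'
#' All denominator roots strictly in the open left half-plane.
#'
#' @param tf An `rtf`.
#' @param tol Margin on the real part (relative to the pole magnitude).
#' @return Logical.
#' @export
tf_is_stable <- function(tf, tol = 1e-9) {
  p <- tf_poles(tf)
  if (!length(p)) return(TRUE)
  all(Re(p) < -tol * pmax(Mod(p), 1))
}

#' Frequency response
#'
#' Evaluates \eqn{H(j\omega)}, including the exact dead-time phase factor.
#'
#' @param tf An `rtf`.
#' @param w Angular frequencies, rad/s.
#' @return Complex vector of responses.
#' @export
freq_response <- function(tf, w) {
  stopifnot(is_rtf(tf), is.numeric(w))
  s <- complex(real = 0, imaginary = w)
  h <- poly_eval(tf$num, s) / poly_eval(tf$den, s)
  if (tf$dead_time > 0) h <- h * exp(-s * tf$dead_time)
  h
}

#' Gain and phase margins from the frequency response
#'
#' Classical Bode margins: the gain margin is measured at the phase
#' crossover (phase through -180 deg) and the phase margin at the gain
#' crossover (magnitude through 0 dB). Crossings are bracketed on a log
#' frequency grid and refined by root finding. Dead time enters as the exact
#' phase term; the unwrapped phase is used so multiple -180 crossings are
#' seen. When a crossover does not exist the corresponding margin is
#' reported as `Inf` and flagged, the convention for systems that can never
#' reach the critical point.
#'
#' @param tf An `rtf` (must be proper; improper inputs are rejected by the
#'   constructor).
#' @param w_range Frequency search range, rad/s.
#' @param n Number of grid points.
#' @return A list with `gain_margin_db`, `phase_margin_deg`,
#'   `w_phase_crossover`, `w_gain_crossover`, and logical flags
#'   `has_phase_crossover`, `has_gain_crossover`.
#' @examples
#' stability_margins(rtf(1, c(1, 1)))          # first-order lag: both Inf
#' stability_margins(patient_model())          # composite patient model
#' @export
stability_margins <- function(tf, w_range = c(1e-4, 1e6), n = 4000) {
  stopifnot(is_rtf(tf))
  w <- exp(seq(log(w_range[1]), log(w_range[2]), length.out = n))
  h <- freq_response(tf, w)
  mag <- Mod(h)
  ph <- unwrap_phase(Arg(h)) * 180 / pi

  loggain <- function(wi) 20 * log10(Mod(freq_response(tf, wi)))

  # gain crossover: |H| = 1
  gm_db <- Inf; pm <- Inf; wcg <- NA_real_; wcp <- NA_real_
  lg <- 20 * log10(mag)
  ix <- which(lg[-n] * lg[-1] < 0)
  if (length(ix)) {
    i <- ix[1]  # lowest-frequency 0 dB crossing
    wcp <- stats::uniroot(loggain, c(w[i], w[i + 1]), tol = 1e-12)$root
    ph_c <- interp_phase(tf, wcp, w, ph)
    pm <- 180 + ph_c
  }
  # phase crossover(s): phase = -180 (mod -360); use unwrapped phase
  target <- ph + 180
  jx <- which(target[-n] * target[-1] < 0)
  if (length(jx)) {
    # among -180 crossings keep the one with the least gain margin
    gms <- vapply(jx, function(j) {
      f <- function(wi) interp_phase(tf, wi, w, ph) + 180
      wr <- tryCatch(stats::uniroot(f, c(w[j], w[j + 1]), tol = 1e-12)$root,
                     error = function(e) NA_real_)
      if (is.na(wr)) return(c(NA_real_, NA_real_))
      c(wr, -loggain(wr))
    }, numeric(2))
    ok <- !is.na(gms[1, ])
    if (any(ok)) {
      k <- which.min(gms[2, ok])
      wcg <- gms[1, ok][k]
      gm_db <- gms[2, ok][k]
    }
  }
  list(gain_margin_db = gm_db, phase_margin_deg = pm,
       w_phase_crossover = wcg, w_gain_crossover = wcp,
       has_phase_crossover = is.finite(gm_db),
       has_gain_crossover = is.finite(pm))
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  jumps <- round(d / (2 * pi))
  ph - c(0, cumsum(jumps)) * 2 * pi
}

# phase at a single frequency, continuous with the unwrapped grid phase
interp_phase <- function(tf, wi, w, ph_unwrapped_deg) {
  raw <- Arg(freq_response(tf, wi)) * 180 / pi
  near <- ph_unwrapped_deg[findInterval(wi, w, all.inside = TRUE)]
  raw + 360 * round((near - raw) / 360)
}

#' Serialize a transfer function to JSON
#'
#' Writes `{"num": [...], "den": [...], "dead_time": d}`.
#'
#' @param tf An `rtf`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when writing to a file.
#' @export
tf_to_json <- function(tf, path = NULL) {
  stopifnot(is_rtf(tf))
  js <- jsonlite::toJSON(list(num = tf$num, den = tf$den,
                              dead_time = tf$dead_time),
                         digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a transfer function from JSON
#'
#' @param path File path or JSON string as written by [tf_to_json()].
#' @return An `rtf`.
#' @export
tf_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  rtf(x$num, x$den, dead_time = if (is.null(x$dead_time)) 0 else x$dead_time)
}
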