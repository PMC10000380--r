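#' Oxygen cylinder / concentrator lag
#'
#' First-order valve-plus-capacity model of the oxygen source,
#' \eqn{1/(\tau s + 1)} with unity DC gain. A patient needing more oxygen
#' corresponds to a larger capacity C and a smaller valve resistance R;
#' \eqn{\tau = RC}. The simulation default is 0.50 s.
#'
#' @param tau Time constant, s (> 0).
#' @return An `rtf`.
#' @export
cylinder_tf <- function(tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number")
  rtf(1, c(tau, 1))
}

#' Canonical second-order airway-segment specifications
#'
#' The four lumped sections of the airway tree (nasal cavity, trachea,
#' bronchi, healthy alveoli), each an RLC biquad
#' \eqn{1/(LC s^2 + RC s + 1)}. Two coefficient sources are available:
#'
#' * `"equation"` (default, canonical for simulation): the s^2 and s
#'   coefficients exactly as used by the published segment transfer
#'   functions;
#' * `"table"`: the products of the printed per-section R, L, C values.
#'
#' The two differ slightly for the nasal s-coefficient (2.165 vs
#' 16.3327 x 0.132 = 2.156) and the bronchi s^2 coefficient (1.44e-5 vs
#' 6.35e-6 x ... from the L column); the equation path is the source of
#' truth and the table path exists for cross-validation.
#'
#' @param source `"equation"` or `"table"`.
#' @return Data frame with columns `label`, `LC`, `RC` (and, for
#'   `"table"`, the underlying `R`, `L`, `C` columns).
#' @export
segment_specs <- function(source = c("equation", "table")) {
  source <- match.arg(source)
  if (source == "equation") {
    data.frame(
      label = c("nasal", "trachea", "bronchi", "alveoli"),
      LC = c(2.7e-3, 3.7e-4, 1.44e-5, 6.72e-8),
      RC = c(2.165, 5.4e-3, 4.02e-4, 5.71e-4),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.frame(
      label = c("nasal", "trachea", "bronchi", "alveoli"),
      R = c(16.3327, 0.086, 0.0087, 0.00055),
      L = c(0.02, 0.0059, 0.0002929, 6.47e-8),
      C = c(0.132, 0.0631, 0.0461, 1.0396),
      stringsAsFactors = FALSE
    )
    tab$RC <- tab$R * tab$C
    tab$LC <- tab$L * tab$C
    tab
  }
}

#' Second-order transfer function of one airway segment
#'
#' \eqn{1/(LC\,s^2 + RC\,s + 1)}: the voltage-divider response of the
#' segment's series R-L, shunt-C electrical analog. Unity DC gain by
#' construction.
#'
#' @param spec Either a segment label (`"nasal"`, `"trachea"`, `"bronchi"`,
#'   `"alveoli"`) or a list/one-row data frame with fields `LC` and `RC`.
#' @param source Coefficient source when `spec` is a label; see
#'   [segment_specs()].
#' @return An `rtf`.
#' @examples
#' segment_tf("trachea")
#' @export
segment_tf <- function(spec, source = c("equation", "table")) {
  if (is.character(spec)) {
    tab <- segment_specs(match.arg(source))
    i <- match(spec, tab$label)
    if (is.na(i)) stop("unknown segment label '", spec, "'")
    spec <- tab[i, ]
  }
  LC <- as.numeric(spec$LC)
  RC <- as.numeric(spec$RC)
  if (!is.finite(LC) || LC <= 0) stop("LC must be positive")
  if (!is.finite(RC) || RC <= 0) stop("RC must be positive")
  rtf(1, c(LC, RC, 1))
}

#' Alveolar segment of a respiratory distress patient
#'
#' In severe respiratory infection the alveolar sacs stiffen and their
#' compliance drops by two to three orders of magnitude. The published
#' distressed-alveoli biquad is returned verbatim:
#' \eqn{1/(1.0\times 10^{-10} s^2 + 1.15\times 10^{-6} s + 1)}.
#'
#' @return An `rtf`.
#' @export
infected_alveoli_tf <- function() {
  rtf(1, c(1.0e-10, 1.15e-6, 1))
}

#' Airway cascade transfer function
#'
#' Series combination nasal x trachea x bronchi x alveoli; the alveolar
#' factor is the healthy biquad or the stiffened (infected) one. The result
#' has an order-8 denominator and unity DC gain.
#'
#' @param condition `"infected"` (default) or `"healthy"`.
#' @return An `rtf`.
#' @export
airway_cascade <- function(condition = c("infected", "healthy")) {
  condition <- match.arg(condition)
  alv <- if (condition == "infected") infected_alveoli_tf()
         else segment_tf("alveoli")
  tf_series(segment_tf("nasal"), segment_tf("trachea"),
            segment_tf("bronchi"), alv)
}

#' Reference model for SpO2 tracking
#'
#' The fixed second-order reference \eqn{1/(s^2 + 2.5 s + 1)} that the
#' adaptive controllers force the patient output to follow. Critically
#' damped-ish (poles at -0.5 and -2), unity DC gain.
#'
#' @return An `rtf`.
#' @export
reference_model_tf <- function() {
  rtf(1, c(1, 2.5, 1))
}
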