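FUZZY_LABELS <- c("NB", "NM", "ZE", "PM", "PB")

#' Triangular fuzzy partition of a universe
#'
#' Five equal-base-width triangular membership functions with 50% overlap
#' (adjacent memberships sum to 1 between centers), labelled NB, NM, ZE,
#' PM, PB, with peaks evenly spaced from `lo` to `hi`. The boundary labels
#' peak at the universe edges. Inputs outside the universe are clamped to
#' the boundary before membership evaluation.
#'
#' @param lo,hi Universe bounds (`lo < hi`).
#' @return An object of class `fuzzy_partition` with fields `lo`, `hi`,
#'   `labels`, `centers`, `halfwidth`.
#' @examples
#' fuzzy_partition(-100, 100)  # error universe, % SpO2
#' fuzzy_partition(-1, 1)      # adaptation-gain universe
#' @export
fuzzy_partition <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 ||
      length(hi) != 1 || !is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("need finite bounds with lo < hi")
  centers <- seq(lo, hi, length.out = 5)
  structure(list(lo = lo, hi = hi, labels = FUZZY_LABELS,
                 centers = centers, halfwidth = centers[2] - centers[1]),
            class = "fuzzy_partition")
}

#' Membership degrees of a crisp value in a partition
#'
#' @param x A single number; values outside the universe are clamped.
#' @param p A [fuzzy_partition()].
#' @return Named numeric vector of degrees in `[0, 1]`; at most two are
#'   nonzero and adjacent nonzero degrees sum to 1.
#' @export
membership <- function(x, p) {
  stopifnot(inherits(p, "fuzzy_partition"), is.numeric(x), length(x) == 1)
  x <- min(max(x, p$lo), p$hi)
  d <- pmax(0, 1 - abs(x - p$centers) / p$halfwidth)
  names(d) <- p$labels
  d
}

#' Rule base for the fuzzy adaptation gain
#'
#' A 5x5 map from (e label, de label) to an output label. With no argument
#' the packaged rule table is loaded and checked: exactly 25 entries, all
#' valid labels, every output label used at least once.
#'
#' @param path CSV path (rows = e labels NB..PB, first column `e`, columns
#'   NB..PB = de labels), or `NULL` for the packaged table.
#' @return A 5x5 character matrix with e labels as rownames and de labels
#'   as colnames, class `fuzzy_rule_base`.
#' @export
rule_base <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fuzzy_rules.csv",
                        package = "respox", mustWork = TRUE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!identical(names(raw)[1], "e") ||
      !identical(names(raw)[-1], FUZZY_LABELS) ||
      !identical(raw$e, FUZZY_LABELS))
    stop("rule CSV must have rows NB..PB (column 'e') and columns NB..PB")
  m <- as.matrix(raw[, -1])
  rownames(m) <- raw$e
  if (length(m) != 25 || !all(m %in% FUZZY_LABELS))
    stop("rule base must contain exactly 25 valid labels")
  if (!all(FUZZY_LABELS %in% m))
    stop("every output label must appear at least once")
  structure(m, class = c("fuzzy_rule_base", "matrix"))
}

#' Fuzzy inference system producing the adaptation gain
#'
#' Mamdani-type inference from the model-following error `e` and its rate
#' `de` to the adaptation gain `m`: triangular partitions on `[-100, 100]`
#' (% SpO2 units) for both inputs and on `[-1, 1]` for the output, the
#' packaged 25-rule base, product conjunction/implication (scaled
#' consequents), max aggregation, and centroid defuzzification on a
#' discretized output universe. Product rather than min implication is
#' used because it keeps the inferred gain monotone along the e = de
#' diagonal (see the methods vignette); both are standard Mamdani
#' variants.
#'
#' @param e_partition,de_partition Input partitions, default
#'   `fuzzy_partition(-100, 100)`.
#' @param m_partition Output partition, default `fuzzy_partition(-1, 1)`.
#' @param rules A [rule_base()].
#' @param n_grid Output discretization (odd, so the grid contains 0 and is
#'   symmetric; centroids of symmetric aggregates are then exactly 0).
#' @return An object of class `fuzzy_gain_system`.
#' @export
fuzzy_gain_system <- function(e_partition = fuzzy_partition(-100, 100),
                              de_partition = fuzzy_partition(-100, 100),
                              m_partition = fuzzy_partition(-1, 1),
                              rules = rule_base(),
                              n_grid = 201) {
  stopifnot(inherits(e_partition, "fuzzy_partition"),
            inherits(de_partition, "fuzzy_partition"),
            inherits(m_partition, "fuzzy_partition"),
            inherits(rules, "fuzzy_rule_base"))
  if (n_grid < 11 || n_grid %% 2 == 0) stop("n_grid must be odd and >= 11")
  # symmetric grid built from the positive half so z and -z pair exactly
  half <- seq(0, 1, length.out = (n_grid + 1) / 2)
  unit <- c(-rev(half[-1]), half)
  z <- m_partition$lo + (unit + 1) / 2 * (m_partition$hi - m_partition$lo)
  out_mf <- vapply(m_partition$centers,
                   function(ctr) pmax(0, 1 - abs(z - ctr) / m_partition$halfwidth),
                   numeric(length(z)))
  # rule index: rule_out[i, j] = output label index for e label i, de label j
  rule_out <- matrix(match(unclass(rules), FUZZY_LABELS), 5, 5)
  structure(list(e_partition = e_partition, de_partition = de_partition,
                 m_partition = m_partition, rules = rules,
                 rule_out = rule_out, z = z, out_mf = out_mf),
            class = "fuzzy_gain_system")
}

#' Infer the adaptation gain from error and error rate
#'
#' Evaluates the Mamdani system: memberships of `e` and `de`, rule
#' strengths by product conjunction, per-output-label max aggregation of
#' scaled consequents, centroid defuzzification. The result is clamped to
#' the output universe. If no rule fires (impossible under input clamping,
#' kept as a guard) the gain is 0 with a warning.
#'
#' @param e Model-following error (y - ym), % SpO2.
#' @param de Error rate, %/s.
#' @param sys A [fuzzy_gain_system()].
#' @return The adaptation gain m in `[-1, 1]`.
#' @examples
#' sys <- fuzzy_gain_system()
#' infer_gain(0, 0, sys)       # 0: only the ZE x ZE -> ZE rule fires
#' infer_gain(100, 100, sys)   # strongly positive: oxygen must be reduced
#' @export
infer_gain <- function(e, de, sys) {
  stopifnot(inherits(sys, "fuzzy_gain_system"))
  if (!is.finite(e) || !is.finite(de)) stop("e and de must be finite")
  me <- membership(e, sys$e_partition)
  md <- membership(de, sys$de_partition)
  w <- outer(me, md)                     # product conjunction
  lev <- numeric(5)
  for (k in which(w > 0)) {
    L <- sys$rule_out[k]
    if (w[k] > lev[L]) lev[L] <- w[k]    # max aggregation per label
  }
  if (all(lev == 0)) {
    warning("no fuzzy rule fired; returning 0")
    return(0)
  }
  agg <- do.call(pmax, c(list(0), lapply(which(lev > 0), function(L)
    sys$out_mf[, L] * lev[L])))
  s <- sum(agg)
  m <- sum(sys$z * agg) / s
  min(max(m, sys$m_partition$lo), sys$m_partition$hi)
}

#' Fuzzy control surface over the (e, de) grid
#'
#' Evaluates [infer_gain()] on an equispaced `grid_n` x `grid_n` grid over
#' the input universes. Used by the property suite (boundedness, corner
#' signs, diagonal monotonicity, refinement continuity) and for surface
#' plots.
#'
#' @param sys A [fuzzy_gain_system()].
#' @param grid_n Grid resolution per axis (>= 3).
#' @return A list with vectors `e`, `de` and the `grid_n` x `grid_n`
#'   matrix `m` (rows index e, columns de).
#' @export
control_surface <- function(sys = fuzzy_gain_system(), grid_n = 101) {
  stopifnot(inherits(sys, "fuzzy_gain_system"))
  if (grid_n < 3) stop("grid_n must be >= 3")
  e <- seq(sys$e_partition$lo, sys$e_partition$hi, length.out = grid_n)
  de <- seq(sys$de_partition$lo, sys$de_partition$hi, length.out = grid_n)
  m <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n))
    for (j in seq_len(grid_n))
      m[i, j] <- infer_gain(e[i], de[j], sys)
  list(e = e, de = de, m = m)
}
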