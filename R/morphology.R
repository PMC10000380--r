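#' Physical properties of air and unit-conversion constants
#'
#' The morphometry formulas are evaluated in cgs units (g, cm, s, dyn) and
#' the results converted to the clinical unit system used throughout the
#' package: pressures in cm H2O and volumes in litres. The defaults are
#' standard air at roughly 20 degrees C, which reproduce the reference
#' per-generation R and L values within a few percent.
#'
#' @param mu Dynamic viscosity of air, g/(cm s) (poise). Default 1.81e-4.
#' @param rho Density of air, g/cm^3. Default 1.225e-3.
#' @param p_cmH2O dyn/cm^2 per cm H2O. Default 980.665.
#' @param v_L cm^3 per litre. Default 1000.
#' @return An object of class `air_properties`.
#' @export
air_properties <- function(mu = 1.81e-4, rho = 1.225e-3,
                           p_cmH2O = 980.665, v_L = 1000) {
  vals <- c(mu = mu, rho = rho, p_cmH2O = p_cmH2O, v_L = v_L)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("air property '", nm, "' must be a single positive finite number")
  }
  structure(as.list(vals), class = "air_properties")
}

# pressure-per-flow conversion: dyn s/cm^5 (cgs) -> cm H2O / (L/s)
cgs_to_clinical_R <- function(air) air$v_L / air$p_cmH2O

check_generation <- function(g) {
  need <- c("n", "d", "l", "s", "u")
  for (nm in need) {
    if (is.null(g[[nm]])) stop("airway generation is missing field '", nm, "'")
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("airway generation field '", nm, "' must be a single positive number")
  }
  invisible(g)
}

#' One generation of the dichotomously branching airway tree
#'
#' A Weibel-type generation: generation `z` contains `n` identical parallel
#' branches (for the shipped morphometry, `n = 2^z`), each of diameter `d`
#' and length `l`; `s` is the *total* cross-sectional area of the generation
#' and `u` the mean air-flow velocity through it.
#'
#' @param z Generation index (integer >= 0).
#' @param n Number of airways in the generation.
#' @param d Single-airway diameter, cm.
#' @param l Airway length, cm.
#' @param s Total cross-sectional area of the generation, cm^2.
#' @param u Mean air-flow velocity, cm/s.
#' @return An object of class `airway_generation`.
#' @export
airway_generation <- function(z, n, d, l, s, u) {
  if (!is.numeric(z) || length(z) != 1 || z < 0 || z != round(z))
    stop("z must be a non-negative integer")
  g <- structure(list(z = as.integer(z), n = n, d = d, l = l, s = s, u = u),
                 class = "airway_generation")
  check_generation(g)
  g
}

#' Poiseuille flow resistance of an airway generation
#'
#' Laminar (Poiseuille) resistance of a single branch,
#' \eqn{8 \mu l / (\pi r^4)} with \eqn{r = d/2}, combined in parallel over
#' the generation's `n` identical branches (division by `n`), and converted
#' from cgs to cm H2O/(L/s).
#'
#' @param g An [airway_generation()] (or any list with fields n, d, l, s, u).
#' @param air An [air_properties()].
#' @return Resistance in cm H2O/(L/s).
#' @examples
#' air <- air_properties()
#' generation_resistance(airway_generation(0, 1, 1.8, 12, 2.54, 197), air)
#' @export
generation_resistance <- function(g, air = air_properties()) {
  check_generation(g)
  r <- g$d / 2
  R_cgs <- 8 * air$mu * g$l / (pi * r^4) / g$n
  R_cgs * cgs_to_clinical_R(air)
}

#' Inertance of an airway generation
#'
#' Gas-column inertia \eqn{\rho l / s}, with `s` the listed *total*
#' generation cross-section (the parallel combination is already folded into
#' the total area), converted from cgs to cm H2O/(L/s^2).
#'
#' @inheritParams generation_resistance
#' @return Inertance in cm H2O/(L/s^2).
#' @export
generation_inertance <- function(g, air = air_properties()) {
  check_generation(g)
  L_cgs <- air$rho * g$l / g$s
  L_cgs * cgs_to_clinical_R(air)
}

#' Compliance of an airway generation
#'
#' \eqn{l s / (\rho n u^2)}, converted from cgs (cm^5/dyn) to L/cm H2O.
#'
#' @inheritParams generation_resistance
#' @return Compliance in L/cm H2O.
#' @export
generation_compliance <- function(g, air = air_properties()) {
  check_generation(g)
  C_cgs <- g$l * g$s / (air$rho * g$n * g$u^2)
  C_cgs / cgs_to_clinical_R(air)
}

#' Per-generation R, L, C for a whole morphometry table
#'
#' Applies the three electrical-analogy formulas row by row.
#'
#' @param geometry Data frame with columns `z, n, d_cm, l_cm, s_cm2, u_cm_s`
#'   (as produced by [read_airway_geometry()]).
#' @param air An [air_properties()].
#' @return The input data frame with columns `R`, `L`, `C` appended
#'   (cm H2O/(L/s), cm H2O/(L/s^2), L/cm H2O).
#' @export
build_morphology_table <- function(geometry, air = air_properties()) {
  if (!is.data.frame(geometry) || nrow(geometry) == 0)
    stop("geometry must be a nonempty data frame")
  need <- c("z", "n", "d_cm", "l_cm", "s_cm2", "u_cm_s")
  miss <- setdiff(need, names(geometry))
  if (length(miss))
    stop("geometry is missing columns: ", paste(miss, collapse = ", "))
  out <- geometry
  out$R <- out$L <- out$C <- NA_real_
  for (i in seq_len(nrow(geometry))) {
    g <- tryCatch(
      airway_generation(geometry$z[i], geometry$n[i], geometry$d_cm[i],
                        geometry$l_cm[i], geometry$s_cm2[i],
                        geometry$u_cm_s[i]),
      error = function(e) stop("row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    out$R[i] <- generation_resistance(g, air)
    out$L[i] <- generation_inertance(g, air)
    out$C[i] <- generation_compliance(g, air)
  }
  out
}

#' Read an airway morphometry table
#'
#' Reads a CSV with header `z,n,d_cm,l_cm,s_cm2,u_cm_s` (additional columns
#' are kept). With no argument, returns the packaged 24-generation
#' morphometry fixture, which also carries the reference `R_ref`, `L_ref`,
#' `C_ref` columns transcribed verbatim from the source table (including its
#' known generation-0 compliance anomaly; see the methods vignette). The
#' fixture values are never recomputed silently.
#'
#' @param path CSV path; `NULL` for the packaged table.
#' @return A data frame.
#' @export
read_airway_geometry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "airway_morphometry.csv",
                        package = "respox", mustWork = TRUE)
  geo <- utils::read.csv(path, comment.char = "#")
  need <- c("z", "n", "d_cm", "l_cm", "s_cm2", "u_cm_s")
  miss <- setdiff(need, names(geo))
  if (length(miss))
    stop("geometry file is missing columns: ", paste(miss, collapse = ", "))
  geo
}

#' Write a morphology table (geometry + R, L, C) to CSV
#'
#' @param tab Data frame from [build_morphology_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphology_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
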