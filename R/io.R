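scenario_field_names <- c("name", "setpoint_profile", "cylinder_tau",
                          "condition", "input_delay", "intermediate_delay",
                          "gas_model_variant", "controller", "duration",
                          "dt", "noise", "reference_drive", "sweep")

#' Serialize a scenario to YAML
#'
#' @param sc A [scenario()].
#' @param path Output path; `NULL` returns the YAML string.
#' @return The YAML string, invisibly when writing to a file.
#' @export
write_scenario_yaml <- function(sc, path = NULL) {
  stopifnot(inherits(sc, "scenario"))
  x <- unclass(sc)
  x$setpoint_profile <- list(time = as.numeric(x$setpoint_profile$time),
                             value = as.numeric(x$setpoint_profile$value))
  x <- x[!vapply(x, is.null, logical(1))]
  txt <- yaml::as.yaml(list(scenario = x), precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Load and validate a scenario from YAML
#'
#' Schema-validated: the file must contain a single `scenario` block,
#' unknown keys are rejected with a message naming them, missing keys are
#' filled with the documented defaults of [scenario()] (a missing
#' controller block becomes the SFPIMRAC defaults), and every invariant of
#' the constructor is enforced.
#'
#' @param path YAML file path.
#' @return A [scenario()].
#' @export
load_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  x <- raw$scenario
  if (is.null(x)) stop("YAML must contain a 'scenario' block")
  unknown <- setdiff(names(x), scenario_field_names)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  sweep <- x$sweep
  x$sweep <- NULL
  if (!is.null(x$setpoint_profile)) {
    sp <- x$setpoint_profile
    if (is.list(sp) && !is.null(sp$time)) {
      x$setpoint_profile <- data.frame(time = as.numeric(sp$time),
                                       value = as.numeric(sp$value))
    } else {
      x$setpoint_profile <- as.numeric(sp)
    }
  }
  for (nm in c("cylinder_tau", "input_delay", "intermediate_delay",
               "duration", "dt"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(x[[nm]])
  sc <- do.call(scenario, x)
  if (!is.null(sweep)) {
    sweep$values <- if (is.character(sweep$values)) as.character(sweep$values)
                    else as.numeric(sweep$values)
    sc$sweep <- list(param = sweep$param, values = sweep$values)
  }
  sc
}

#' Write simulation trajectories to CSV
#'
#' Column order `t,r,r_mod,u,y,ym,e,theta,m`; byte-identical output for
#' identical inputs.
#'
#' @param res A `simulation_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(res, path) {
  stopifnot(inherits(res, "simulation_result"))
  utils::write.csv(res$trajectories, path, row.names = FALSE)
  invisible(path)
}

#' Read simulation trajectories from CSV
#'
#' @param path CSV path written by [write_result_csv()].
#' @param sc Optional [scenario()] to attach (metrics need the step size;
#'   if absent, dt is inferred from the time grid).
#' @return A `simulation_result`.
#' @export
read_result_csv <- function(path, sc = NULL) {
  tr <- utils::read.csv(path)
  need <- c("t", "r", "r_mod", "u", "y", "ym", "e", "theta", "m")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trajectory CSV is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(sc)) {
    dt <- stats::median(diff(tr$t))
    sc <- scenario(name = "loaded", duration = max(tr$t), dt = dt)
  }
  structure(list(scenario = sc, trajectories = tr),
            class = "simulation_result")
}

#' Write performance metrics to JSON
#'
#' @param metrics A `performance_metrics` (or named list of them).
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when writing to a file.
#' @export
write_metrics_json <- function(metrics, path = NULL) {
  strip <- function(m) lapply(unclass(m), function(v)
    if (is.numeric(v) && length(v) == 1 && is.nan(v)) NA else v)
  x <- if (inherits(metrics, "performance_metrics")) strip(metrics)
       else lapply(metrics, strip)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Manifest describing one simulation run
#'
#' Records what produced an output: scenario name, a hash of the full
#' scenario configuration (stable for identical configs), package version,
#' seed, and output paths.
#'
#' @param sc A [scenario()].
#' @param seed Seed used (or `NA`).
#' @param outputs Character vector of output paths.
#' @return A list; write it with [yaml::write_yaml()] next to the outputs.
#' @export
run_manifest <- function(sc, seed = NA, outputs = character()) {
  stopifnot(inherits(sc, "scenario"))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(write_scenario_yaml(sc), tmp)
  hash <- unname(tools::md5sum(tmp))
  list(scenario = sc$name, config_md5 = hash,
       package_version = as.character(utils::packageVersion("respox")),
       seed = seed, outputs = as.list(outputs))
}
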