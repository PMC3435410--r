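# File I/O: YAML parameter files, trajectory CSV, fixture CSV, fit-report
# JSON. CSV uses '.' decimal, UTF-8, LF line endings.

#' Read a parameter file
#'
#' YAML (or JSON) file with primary-parameter names; sections are allowed
#' (nested maps are flattened) and unknown keys are rejected.
#'
#' @param path file path
#' @return validated \code{prostasim_params}
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  flatten <- function(x) for (nm in names(x)) {
    if (is.list(x[[nm]])) flatten(x[[nm]])
    else flat[[nm]] <<- x[[nm]]
  }
  flatten(raw)
  prostasim_params(.list = flat)
}

#' Write the primary parameters to a YAML file
#'
#' @param p parameter set
#' @param path file path
#' @export
write_params <- function(p, path) {
  prim <- lapply(names(prostasim_defaults()), function(nm) p[[nm]])
  names(prim) <- names(prostasim_defaults())
  yaml::write_yaml(prim, path)
  invisible(path)
}

#' Write a simulation trajectory to CSV
#'
#' First column \code{time_hr}, then the state columns in canonical order,
#' then derived observables prefixed \code{obs_}.
#'
#' @param sim a \code{prostasim_sim}
#' @param path file path
#' @export
write_trajectory <- function(sim, path) {
  df <- as.data.frame(sim)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read/write a fixture data set (CSV)
#'
#' Columns \code{arm, day, observable, value, replicate}.
#'
#' @param fixture fixture data.frame
#' @param path file path
#' @export
write_fixture <- function(fixture, path) {
  utils::write.csv(fixture, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm", "day", "observable", "value")
  if (!all(need %in% names(fx)))
    stop("fixture file must have columns: ", paste(need, collapse = ", "))
  fx
}

#' Write a calibration report to JSON
#'
#' One record per fitted parameter: \code{parameter, fitted, se,
#' residual_norm}.
#'
#' @param fit a \code{prostasim_fit}
#' @param path file path
#' @export
write_fit_report <- function(fit, path) {
  rep <- lapply(seq_along(fit$free), function(i) list(
    parameter = fit$free[i],
    fitted = unname(fit$par[i]),
    se = unname(fit$se[i]),
    residual_norm = fit$residual_norm))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
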