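#' Write and read structured configuration files
#'
#' Parameter sets serialize to YAML or JSON (by file extension).  Only
#' primary fields are stored; derived quantities (calibrated gains,
#' baselines, `Kd`) are recomputed on read by the constructors.
#'
#' @param x A list or parameter object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `config_read` returns a list; `config_write` returns `path`
#'   invisibly.
#' @export
config_write <- function(x, path) {
  x <- unclass(x)
  x <- x[!vapply(x, function(e) is.numeric(e) && length(e) > 1, logical(1))]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# Rebuild a parameter object from a config list, keeping only arguments
# the constructor knows.
.from_config <- function(constructor, lst, fixed = character()) {
  keep <- intersect(names(lst), names(formals(constructor)))
  keep <- setdiff(keep, fixed)
  do.call(constructor, lst[keep])
}

#' @rdname config_write
#' @export
physio_params_from_config <- function(path) {
  .from_config(physio_params, config_read(path))
}

#' @rdname config_write
#' @param drug,route Passed to the constructor when absent from the file.
#' @export
pk_params_from_config <- function(path, drug = NULL, route = NULL) {
  lst <- config_read(path)
  if (!is.null(drug)) lst$drug <- drug
  if (!is.null(route)) lst$route <- route
  keep <- intersect(names(lst), c("drug", "route", "V1", "V2", "CL", "Q",
                                  "ka", "F"))
  do.call(pk_params, lst[keep])
}

#' Export a simulated trajectory as long-format CSV
#'
#' @param sim An `overdose_sim` object.
#' @param path Output CSV path.
#' @param vars Trajectory columns to export (default all).
#' @return `path` invisibly.
#' @export
trajectory_to_csv <- function(sim, path, vars = NULL) {
  tr <- sim$trajectory
  if (is.null(vars)) vars <- setdiff(names(tr), "t")
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(t = tr$t, variable = v, value = tr[[v]])))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
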