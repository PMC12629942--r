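# Run-configuration files (JSON or YAML) for the command-line interface and
# reproducible runs. A run config may carry a `simulate` section (overrides
# for default_sim_config) and a `model` section (overrides for
# default_model_config).

#' Read a run configuration file
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Named list with (optional) `simulate` and `model` sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) stop("config must be a mapping")
  cfg
}

#' Build simulation / model configurations from a run config
#'
#' @param run_config List from [read_run_config()].
#' @return For `sim_config_from_run`: a [default_sim_config()] list with the
#'   `simulate` overrides applied; for `model_config_from_run`: a
#'   [default_model_config()] list with the `model` overrides applied.
#' @export
sim_config_from_run <- function(run_config) {
  over <- run_config$simulate
  if (is.null(over)) return(default_sim_config())
  do.call(default_sim_config, over)
}

#' @rdname sim_config_from_run
#' @export
model_config_from_run <- function(run_config) {
  over <- run_config$model
  if (is.null(over)) return(default_model_config())
  cfg <- default_model_config()
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown model config field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else if (nm == "weights") {
      w <- cfg$weights
      w[names(over[[nm]])] <- unlist(over[[nm]])
      cfg$weights <- w
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}
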