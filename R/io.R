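#' Read a run configuration
#'
#' A YAML file describing a run: optional `parameters` (path to a parameter
#' TSV; defaults to the packaged set), `scenario` (diet protocol and/or
#' intervention), `solver` options, `seed` and `out` directory. Unknown keys
#' are preserved.
#'
#' @param path Path to a YAML file.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(parameters = NULL, seed = 1, out = ".",
                   solver = list(rtol = 1e-8, atol = 1e-10))
  cfg <- modifyList(defaults, cfg %||% list())
  if (!is.null(cfg$parameters) && !file.exists(cfg$parameters)) {
    abort(paste0("parameter file not found: ", cfg$parameters))
  }
  cfg
}

#' Write a trajectory as tidy CSV
#'
#' One row per time point; columns `time`, one per species, plus the
#' normalized observables when present.
#'
#' @param trajectory A `cd_trajectory` (or scenario trajectory) tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(as_tibble(as.data.frame(trajectory)), path,
                   progress = FALSE)
  invisible(path)
}

#' Write endpoint observables as JSON
#'
#' @param x A tibble or named list of scalars.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_endpoint_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a species table
#'
#' A species file mirrors the model's state list: columns `species` (name),
#' `initial_value` and `compartment` (`lumen`, `lamina`, `epithelium` or
#' `plasma`). The packaged file `extdata/species.tsv` carries the default
#' initial guess.
#'
#' @param path Path to a TSV file; default the packaged table.
#' @return A tibble with one row per species.
#' @export
read_species <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species.tsv", package = "celiacqsp",
                        mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "initial_value", "compartment")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("species table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(tab$initial_value < 0)) abort("initial values must be >= 0")
  tab
}

#' Read a calibration dataset from CSV
#'
#' Columns `observable`, `condition`, `value`, and optionally `weight` and
#' `bound`; see [calibration_dataset()].
#'
#' @param path Path to a CSV file.
#' @return A `cd_dataset` tibble.
#' @export
read_calibration_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  calibration_dataset(tab$observable, tab$condition, tab$value,
                      weight = tab$weight %||% NULL,
                      bound = tab$bound %||% "eq")
}
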