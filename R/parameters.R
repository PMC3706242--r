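#' Reference parameter set
#'
#' Loads the parameter table shipped with the package. The primary study's
#' full parameter table is not included here, so the shipped table is a
#' synthetic reference set: the structural constants
#' follow the literature-anchored magnitudes described in the methods
#' vignette and the free constants were re-fitted by pattern search against
#' the printed calibration anchors (villous area 100/50/10% for
#' healthy/gluten-free/gluten diet, antibody normalization, diet-switch
#' transient times, and the 5-fold native:deamidated EC50 ratio).
#'
#' @return A `cd_params` tibble with columns `name`, `value`, `unit`,
#'   `source` (one of `"literature"`, `"assumed"`, `"calculated"`,
#'   `"fitted"`), `ci_lo`, `ci_hi` and `description`. The patient model has
#'   exactly 54 parameters.
#' @examples
#' params <- cd_parameters()
#' nrow(params)
#' @export
cd_parameters <- function() {
  path <- system.file("extdata", "parameters_synthetic.tsv",
                      package = "celiacqsp", mustWork = TRUE)
  read_parameters(path)
}

#' Read a parameter table from a delimited file
#'
#' Expects tab-separated columns `name`, `value`, `unit`, `source`, `ci_lo`,
#' `ci_hi` (an optional `description` column is carried along). The table is
#' validated: duplicate names, negative values, or an interval with
#' `ci_lo > ci_hi` (or not bracketing the value) are errors; a parameter
#' count other than 54 is only a warning, so reduced test models can be
#' loaded.
#'
#' @param path Path to a TSV file.
#' @return A validated `cd_params` tibble.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  validate_parameters(tab)
}

#' Write a parameter table to a TSV file
#'
#' @param params A `cd_params` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  readr::write_tsv(params, path, progress = FALSE)
  invisible(path)
}

#' Validate a parameter table
#'
#' @param tab A data frame of parameters.
#' @return The table with class `cd_params`, or an error describing every
#'   offending row.
#' @export
validate_parameters <- function(tab) {
  required <- c("name", "value", "unit", "source", "ci_lo", "ci_hi")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("parameter table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  dup <- unique(tab$name[duplicated(tab$name)])
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicated parameter(s): ",
                                   paste(dup, collapse = ", ")))
  }
  neg <- tab$name[!is.na(tab$value) & tab$value < 0]
  if (length(neg) > 0) {
    problems <- c(problems, paste0("negative value(s): ",
                                   paste(neg, collapse = ", ")))
  }
  has_ci <- !is.na(tab$ci_lo) & !is.na(tab$ci_hi)
  bad_ci <- tab$name[has_ci & (tab$ci_lo > tab$value | tab$ci_hi < tab$value)]
  if (length(bad_ci) > 0) {
    problems <- c(problems, paste0("interval does not bracket value for: ",
                                   paste(bad_ci, collapse = ", ")))
  }
  bad_src <- tab$name[!tab$source %in%
                        c("literature", "assumed", "calculated", "fitted")]
  if (length(bad_src) > 0) {
    problems <- c(problems, paste0("unknown source tag for: ",
                                   paste(bad_src, collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(paste0("invalid parameter table:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  if (nrow(tab) != 54) {
    warn(paste0("parameter table has ", nrow(tab),
                " parameters (the full patient model has 54)"))
  }
  tab <- as_tibble(tab)
  class(tab) <- unique(c("cd_params", class(tab)))
  tab
}

#' Parameter table as a named numeric vector
#'
#' @param params A `cd_params` tibble (or any data frame with `name` and
#'   `value` columns), or an already-named numeric vector (returned as is).
#' @return Named numeric vector of parameter values.
#' @export
param_vector <- function(params) {
  if (is.numeric(params) && !is.null(names(params))) {
    return(params)
  }
  setNames(params$value, params$name)
}

#' Update parameter values by name
#'
#' @param params A `cd_params` tibble.
#' @param ... Named scalars, e.g. `param_update(p, ksab = 0.2)`.
#' @return The modified table.
#' @examples
#' p <- param_update(cd_parameters(), TG2_level = 0)
#' @export
param_update <- function(params, ...) {
  upd <- list(...)
  if (length(upd) == 0) return(params)
  unknown <- setdiff(names(upd), params$name)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(upd)) {
    params$value[params$name == nm] <- upd[[nm]]
  }
  params
}

#' Fetch a single parameter value
#'
#' @param params A `cd_params` tibble.
#' @param name Parameter name.
#' @return Scalar value.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) abort(paste0("unknown parameter: ", name))
  params$value[i]
}

# Names of the free (fitted) parameters.
cd_fitted_names <- function(params = cd_parameters()) {
  params$name[params$source == "fitted"]
}
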