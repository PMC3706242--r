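#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model
#'
#' @param x A `cd_fit` from [fit_model()].
#' @param ... Unused.
#' @return One row per fitted parameter: `name`, `estimate`, `start`.
#' @method tidy cd_fit
#' @export
tidy.cd_fit <- function(x, ...) {
  tibble(name = names(x$estimate),
         estimate = unname(x$estimate),
         start = unname(x$problem$start[names(x$estimate)]))
}

#' One-line fit summary
#'
#' @param x A `cd_fit`.
#' @param ... Unused.
#' @return One-row tibble: final and initial SSE, iteration and evaluation
#'   counts, convergence flag.
#' @method glance cd_fit
#' @export
glance.cd_fit <- function(x, ...) {
  tibble(sse = x$sse, sse_initial = x$sse_initial,
         n_iter = x$n_iter, n_eval = x$n_eval,
         n_obs = nrow(x$problem$dataset),
         n_free = length(x$problem$free),
         converged = x$converged)
}

#' @export
print.cd_fit <- function(x, ...) {
  cat("<cd_fit> ", length(x$problem$free), " free parameter(s), SSE ",
      format(x$sse_initial, digits = 4), " -> ",
      format(x$sse, digits = 4), " in ", x$n_iter, " iterations\n",
      sep = "")
  invisible(x)
}

#' Summary quantiles of a robustness scan
#'
#' @param x A `cd_robustness` from [robustness_scan()].
#' @param ... Unused.
#' @return One-row tibble with draw counts and 2.5/50/97.5% quantiles of
#'   both observables over the converged draws.
#' @method glance cd_robustness
#' @export
glance.cd_robustness <- function(x, ...) {
  ok <- x[x$converged, ]
  qs <- function(v) quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  ab <- qs(ok$antibody_pct)
  va <- qs(ok$villous_area_pct)
  tibble(kind = attr(x, "kind"), strength = attr(x, "strength"),
         n_draws = nrow(x), n_failed = sum(!x$converged),
         ab_q025 = ab[1], ab_median = ab[2], ab_q975 = ab[3],
         va_q025 = va[1], va_median = va[2], va_q975 = va[3])
}
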