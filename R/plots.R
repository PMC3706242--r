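#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' @param object A `cd_trajectory` from [simulate_model()] or the
#'   `trajectory` element of a [run_diet_switch()] result.
#' @param species Species to show (default: all state variables present).
#' @param ... Unused.
#' @return A ggplot: one facet per species, free y scales.
#' @method autoplot cd_trajectory
#' @export
autoplot.cd_trajectory <- function(object, species = NULL, ...) {
  keep <- setdiff(names(object),
                  c("time", "antibody_pct", "villous_area_pct"))
  if (!is.null(species)) keep <- intersect(keep, species)
  long <- tidyr::pivot_longer(object[, c("time", keep)], -time,
                              names_to = "species", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(time, value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "level (a.u.)")
}

#' Plot normalized observables along a diet-switch scenario
#'
#' @param scenario A `cd_scenario` from [run_diet_switch()].
#' @return A ggplot of antibody level and villous area (% of reference)
#'   versus time, with switch times marked.
#' @export
plot_diet_switch <- function(scenario) {
  tr <- scenario$trajectory
  long <- tidyr::pivot_longer(
    tr[, c("time", "antibody_pct", "villous_area_pct")], -time,
    names_to = "observable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(time, value, colour = observable)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = scenario$protocol$time[-1],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (days)", y = "% of reference", colour = NULL)
}

#' Plot an intervention dose-response curve
#'
#' @param object A `cd_dose_response` from [dose_response()].
#' @param ... Unused.
#' @return A ggplot of antibody level and villous area versus intervention
#'   strength.
#' @method autoplot cd_dose_response
#' @export
autoplot.cd_dose_response <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("kind", "strength", "antibody_pct", "villous_area_pct")],
    c("antibody_pct", "villous_area_pct"),
    names_to = "observable", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(strength, value, colour = kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~observable) +
    ggplot2::labs(x = "intervention strength", y = "% of reference")
}
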