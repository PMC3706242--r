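#' Normalized observables: antibody level and villous area
#'
#' The model's two clinical readouts. The antibody level is expressed as a
#' percentage of the steady-state antibody level of an untreated patient on
#' a gluten-containing diet (so the untreated gluten-diet steady state is
#' 100% by construction). The villous area is proxied by the mature-IEC
#' level as a percentage of the healthy level (healthy = 100%): epithelial
#' cell loss is the model's only villous-mass variable, and every
#' villous-area statement the model makes is driven by IEC death and
#' maturation.
#'
#' @param state Named state vector (or a `cd_trajectory`, in which case the
#'   observables are computed for every row).
#' @param ref_ab Antibody level at the untreated gluten-diet steady state
#'   (must be > 0).
#' @param ref_iec Healthy mature-IEC level (must be > 0).
#' @return A tibble with columns `antibody_pct` and `villous_area_pct` (and
#'   `time` when a trajectory was supplied).
#' @examples
#' refs <- cd_references(cd_parameters())
#' observables(refs$x_gluten, refs$ref_ab, refs$ref_iec)
#' @export
observables <- function(state, ref_ab, ref_iec) {
  if (!is.finite(ref_ab) || ref_ab <= 0) abort("ref_ab must be > 0")
  if (!is.finite(ref_iec) || ref_iec <= 0) abort("ref_iec must be > 0")
  if (inherits(state, "cd_trajectory") || is.data.frame(state)) {
    return(tibble(
      time = state$time,
      antibody_pct = 100 * state$Ab / ref_ab,
      villous_area_pct = 100 * state$IEC / ref_iec
    ))
  }
  tibble(
    antibody_pct = 100 * state[["Ab"]] / ref_ab,
    villous_area_pct = 100 * state[["IEC"]] / ref_iec
  )
}

#' Reference steady states and normalization constants
#'
#' Computes the three reference steady states of the model -- healthy
#' subject, untreated patient on a gluten-containing diet, and untreated
#' patient on a gluten-free diet -- together with the normalization
#' references: `ref_ab` (gluten-diet antibody level, the 100% antibody
#' anchor) and `ref_iec` (healthy mature-IEC level, the 100% villous-area
#' anchor). The gluten-free state is computed by relaxing from the
#' gluten-diet state, matching the clinical situation of a diagnosed
#' patient changing diet.
#'
#' @param params A [cd_parameters()] table.
#' @return A list with `x_healthy`, `x_gluten`, `x_gfd`, `ref_ab`,
#'   `ref_iec`.
#' @export
cd_references <- function(params) {
  net_h <- build_network(params, "healthy", diet = "gluten")
  x_h <- steady_state(net_h)

  net_g <- build_network(params, "patient", diet = "gluten")
  x_g <- steady_state(net_g)

  net_f <- build_network(params, "patient", diet = "gfd")
  x_f <- steady_state(net_f, x_guess = x_g)

  list(
    x_healthy = x_h,
    x_gluten = x_g,
    x_gfd = x_f,
    ref_ab = x_g[["Ab"]],
    ref_iec = x_h[["IEC"]]
  )
}

#' Summary table of the three reference conditions
#'
#' @param params A [cd_parameters()] table.
#' @return A tibble with one row per condition (healthy, patient on
#'   gluten-free diet, patient on gluten diet) and the normalized
#'   observables.
#' @examples
#' \donttest{cd_condition_table(cd_parameters())}
#' @export
cd_condition_table <- function(params) {
  refs <- cd_references(params)
  dplyr::bind_rows(
    dplyr::mutate(observables(refs$x_healthy, refs$ref_ab, refs$ref_iec),
                  condition = "healthy"),
    dplyr::mutate(observables(refs$x_gfd, refs$ref_ab, refs$ref_iec),
                  condition = "patient_gfd"),
    dplyr::mutate(observables(refs$x_gluten, refs$ref_ab, refs$ref_iec),
                  condition = "patient_gluten")
  ) |>
    dplyr::select(condition, antibody_pct, villous_area_pct)
}
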