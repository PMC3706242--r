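#' Model species
#'
#' The state variables of the celiac-disease immune-response model. The
#' patient model tracks 16 species across four compartments: gluten peptides
#' in the intestinal lumen and lamina propria (native and deamidated, the
#' latter pooling free deamidated peptides with TG-2--peptide complexes),
#' zonulin, mature and activated intestinal epithelial cells (IEC),
#' intraepithelial lymphocytes (IEL, resting and activated/natural-killer),
#' interleukin-15, the merged IFN-gamma + IL-21 cytokine pool (IF-21),
#' DQ2/DQ8 antigen-presenting cells (resting and activated), T cells
#' (resting, transiently activated, activated; Th1 and Th17 are pooled), and
#' circulating antibodies against gluten peptides and TG-2.
#'
#' The healthy variant has no DQ2/DQ8 antigen-presenting cells, so `APC` and
#' `aAPC` are absent and the state has 14 species.
#'
#' @param variant `"patient"` (default) or `"healthy"`.
#' @return A tibble with columns `species`, `compartment` and `description`,
#'   one row per state variable, in canonical state-vector order.
#' @examples
#' cd_species()
#' nrow(cd_species("healthy"))
#' @export
cd_species <- function(variant = c("patient", "healthy")) {
  variant <- match.arg(variant)
  tab <- tibble::tribble(
    ~species,   ~compartment,  ~description,
    "Glut_lum", "lumen",       "native gluten peptides in the intestinal lumen",
    "Glut_lam", "lamina",      "native gluten peptides in the lamina propria",
    "dGlut",    "lamina",      "deamidated gluten peptides (incl. TG-2 complexes)",
    "Zon",      "lumen",       "zonulin",
    "IEC",      "epithelium",  "mature intestinal epithelial cells",
    "aIEC",     "epithelium",  "activated intestinal epithelial cells",
    "IEL",      "epithelium",  "resting intraepithelial lymphocytes",
    "aIEL",     "epithelium",  "activated IEL (natural killers)",
    "IL15",     "lamina",      "interleukin-15",
    "IF21",     "lamina",      "merged IFN-gamma + IL-21 pool",
    "APC",      "lamina",      "resting DQ2/DQ8 antigen-presenting cells",
    "aAPC",     "lamina",      "activated DQ2/DQ8 antigen-presenting cells",
    "Tcell",    "lamina",      "resting T cells (pooled Th1 + Th17)",
    "aTt",      "lamina",      "transiently activated T cells",
    "aT",       "lamina",      "activated T cells",
    "Ab",       "plasma",      "antibodies to gluten peptides and TG-2"
  )
  if (variant == "healthy") {
    tab <- dplyr::filter(tab, !.data$species %in% c("APC", "aAPC"))
  }
  tab
}

#' Species names in state-vector order
#'
#' @param variant `"patient"` or `"healthy"`.
#' @return Character vector of species names.
#' @export
cd_species_names <- function(variant = c("patient", "healthy")) {
  cd_species(variant)$species
}

# Species that are identically zero at the healthy steady state: all
# activated cells, cytokines, zonulin and antibodies.
cd_activation_species <- function() {
  c("aIEC", "aIEL", "IL15", "IF21", "aAPC", "aTt", "aT", "Zon", "Ab",
    "Glut_lam", "dGlut")
}

#' Default initial state
#'
#' A generic non-negative starting point used as an initial guess for
#' steady-state solving and as a default initial condition. Resting cell
#' pools start near their supply/death balance; everything driven by
#' immune activation starts at a small positive seed so that simulations
#' can approach either the quiescent or the inflamed steady state.
#'
#' @param params A [cd_parameters()] table.
#' @param variant `"patient"` or `"healthy"`.
#' @param activation Seed level for activation-driven species (default 0.2).
#' @return Named numeric state vector.
#' @export
cd_initial_state <- function(params, variant = c("patient", "healthy"),
                             activation = 0.2) {
  variant <- match.arg(variant)
  p <- param_vector(params)
  sp <- cd_species_names(variant)
  x <- setNames(rep(activation, length(sp)), sp)
  x["IEC"] <- p[["IEC_healthy"]] / 2
  x["IEL"] <- p[["s_iel"]] / p[["kd_iel"]]
  x["Tcell"] <- p[["s_tcell"]] / p[["kd_tcell"]]
  if ("APC" %in% sp) x["APC"] <- p[["k_apc_basal"]] / p[["kd_apc"]]
  x["Glut_lum"] <- p[["inflow_gluten_diet"]] / p[["kdeg_glum"]]
  x
}
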