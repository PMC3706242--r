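#' Build the celiac-disease reaction network
#'
#' Assembles the reaction network of the innate and adaptive immune response
#' to dietary gluten: each reaction carries an integer stoichiometry over
#' the model species and a non-negative rate law. The patient network has 16
#' species; the healthy variant drops the DQ2/DQ8 antigen-presenting-cell
#' equations and has the IEC- and IEL-activation rates identically zero, so
#' a healthy subject mounts no immune response at any gluten intake.
#'
#' Rate-law structure (numbers refer to the process scheme used throughout
#' the package):
#' * gluten inflow into the lumen is constant (diet-determined) and luminal
#'   peptides decay first order;
#' * transport into the lamina propria (#13) is
#'   `(kz_transport*Zon + ki_transport*max(0, 1 - IEC/IEC_healthy))*Glut_lum`,
#'   the additive zonulin + epithelial-deficit permeability law, zero for an
#'   intact zonulin-free epithelium;
#' * IEC activation (#5) is a steep Hill function of luminal gluten (a
#'   receptor-occupancy threshold), activated IEC secrete zonulin (#31) and
#'   IL-15 (#7);
#' * IEC die (#4, #6) at a basal rate plus contributions from activated IEL,
#'   IF-21 and antibodies; antibodies also inhibit IEC maturation (#3);
#' * IEL are activated by IL-15 (#11) and IL-15 arrests activated-IEL
#'   apoptosis (#10);
#' * TG-2 deamidates lamina peptides (#33); native and deamidated peptides
#'   activate APC (#18) with the deamidated EC50 5-fold below the native
#'   one; IL-15 drives APC differentiation from monocytes (#16);
#' * activated APC prime T cells through a transient compartment (#22, #34)
#'   with an IF-21 boost; activated T cells and activated IEL secrete IF-21
#'   (#23); antibody synthesis (#25) requires activated T cells and lamina
#'   peptides.
#'
#' @param params A [cd_parameters()] table (or named numeric vector). The
#'   patient variant requires all 54 parameters; for the healthy variant the
#'   APC-only parameters may be absent.
#' @param variant `"patient"` (default) or `"healthy"`.
#' @param diet `"gluten"`, `"gfd"`, or a non-negative number giving a custom
#'   constant gluten inflow rate (au/day).
#' @return A `cd_network` object: a list with `species`, `reactions` (a
#'   tibble of id, label and rate expression), the stoichiometric matrix `N`
#'   (species x reactions), and a compiled rate evaluator.
#' @examples
#' net <- build_network(cd_parameters(), "patient")
#' dim(net$N)
#' @export
build_network <- function(params, variant = c("patient", "healthy"),
                          diet = "gluten") {
  variant <- match.arg(variant)
  pvec <- param_vector(params)
  sp <- cd_species_names(variant)

  needed <- cd_network_parameters(variant)
  missing_p <- setdiff(needed, names(pvec))
  if (length(missing_p) > 0) {
    abort(paste0("missing parameter(s): ", paste(missing_p, collapse = ", ")))
  }

  inflow_expr <- if (is.numeric(diet)) {
    if (diet < 0) abort("custom gluten inflow must be non-negative")
    diet
  } else if (identical(diet, "gluten")) {
    quote(inflow_gluten_diet)
  } else if (identical(diet, "gfd")) {
    quote(inflow_gfd)
  } else {
    abort("diet must be \"gluten\", \"gfd\" or a non-negative number")
  }

  rx <- cd_reaction_list(variant, inflow_expr)
  compile_network(sp, rx, pvec, variant, diet)
}

# Assemble a cd_network from species names, a reaction list and parameter
# values (shared by build_network and the SBML importer).
compile_network <- function(sp, rx, pvec, variant, diet) {
  N <- matrix(0L, nrow = length(sp), ncol = length(rx),
              dimnames = list(sp, vapply(rx, `[[`, "", "id")))
  for (j in seq_along(rx)) {
    st <- rx[[j]]$stoich
    N[names(st), j] <- as.integer(st)
  }

  penv <- list2env(as.list(pvec), parent = baseenv())
  exprs <- lapply(rx, `[[`, "rate")
  rate_fun <- function(state) {
    e <- list2env(as.list(state), parent = penv)
    vapply(exprs, eval, numeric(1), envir = e)
  }

  structure(
    list(
      variant = variant,
      diet = diet,
      species = sp,
      reactions = tibble(
        id = vapply(rx, `[[`, "", "id"),
        process = vapply(rx, function(r) r$fig %||% NA_integer_, 0L),
        label = vapply(rx, function(r) r$label %||% r$id, ""),
        rate = I(exprs)
      ),
      stoich = lapply(rx, `[[`, "stoich"),
      N = N,
      rate_fun = rate_fun,
      params = pvec
    ),
    class = "cd_network"
  )
}

# Parameters referenced by the network of each variant.
cd_network_parameters <- function(variant) {
  base <- c(
    "inflow_gluten_diet", "inflow_gfd", "kdeg_glum", "kz_transport",
    "ki_transport", "IEC_healthy", "kdeg_glam", "kcat_deam", "TG2_level",
    "kdeg_dglut", "kmat", "Ki_ab_mat", "kd_iec", "kd_iec_aiel",
    "kd_iec_if21", "kd_iec_ab", "kd_aiec", "k_zon", "kdeg_zon",
    "k_il15_aiec", "kdeg_il15", "s_iel", "kd_iel", "kd_aiel",
    "Ki_il15_apop", "s_tcell", "kd_tcell", "k_trans_t", "kd_att", "kd_at",
    "k_if21_at", "k_if21_aiel", "kdeg_if21", "ksab", "K_ab_pep", "kdeg_ab"
  )
  if (variant == "patient") {
    c(base,
      "k_act_iec", "K_act_iec", "h_act_iec", "k_act_iel", "K_act_iel",
      "h_act_iel", "k_apc_basal", "k_apc_il15", "K_apc_il15", "kd_apc",
      "k_act_apc", "EC50_deam", "EC50_nat", "kd_aapc", "k_act_t",
      "a_if21_t", "K_if21_t", "k_il15_aapc")
  } else {
    base
  }
}

# The reaction list. `fig` gives the process number in the network scheme
# where one exists. Stoichiometries are integer and every rate consuming a
# species is proportional to it, which guarantees non-negativity.
cd_reaction_list <- function(variant, inflow_expr) {
  patient <- variant == "patient"
  rx <- list(
    list(id = "gluten_inflow", fig = 1L, label = "gluten inflow into lumen",
         stoich = c(Glut_lum = 1),
         rate = inflow_expr),
    list(id = "glut_lum_degradation", fig = 2L,
         label = "luminal gluten peptide degradation",
         stoich = c(Glut_lum = -1),
         rate = quote(kdeg_glum * Glut_lum)),
    list(id = "iec_maturation", fig = 3L,
         label = "IEC maturation (antibody-inhibited)",
         stoich = c(IEC = 1),
         rate = quote(kmat / (1 + Ab / Ki_ab_mat))),
    list(id = "iec_death", fig = 4L,
         label = "IEC death (basal + aIEL + IF-21 + antibody driven)",
         stoich = c(IEC = -1),
         rate = quote((kd_iec + kd_iec_aiel * aIEL + kd_iec_if21 * IF21 +
                         kd_iec_ab * Ab) * IEC)),
    list(id = "iec_activation", fig = 5L,
         label = "IEC activation by luminal gluten",
         stoich = c(IEC = -1, aIEC = 1),
         rate = if (patient)
           quote(k_act_iec * IEC * Glut_lum^h_act_iec /
                   (K_act_iec^h_act_iec + Glut_lum^h_act_iec))
         else 0),
    list(id = "aiec_death", fig = 6L,
         label = "activated IEC death",
         stoich = c(aIEC = -1),
         rate = quote((kd_aiec + kd_iec_aiel * aIEL + kd_iec_if21 * IF21 +
                         kd_iec_ab * Ab) * aIEC)),
    list(id = "il15_synthesis", fig = 7L,
         label = "IL-15 synthesis by activated IEC and APC",
         stoich = c(IL15 = 1),
         rate = if (patient)
           quote(k_il15_aiec * aIEC + k_il15_aapc * aAPC)
         else quote(k_il15_aiec * aIEC)),
    list(id = "il15_degradation", fig = 8L,
         label = "IL-15 degradation",
         stoich = c(IL15 = -1),
         rate = quote(kdeg_il15 * IL15)),
    list(id = "iel_supply", fig = 9L,
         label = "IEL supply into the epithelium",
         stoich = c(IEL = 1),
         rate = quote(s_iel + 0)),
    list(id = "aiel_death", fig = 10L,
         label = "activated IEL death (IL-15 arrested)",
         stoich = c(aIEL = -1),
         rate = quote(kd_aiel * aIEL / (1 + IL15 / Ki_il15_apop))),
    list(id = "iel_activation", fig = 11L,
         label = "IEL activation by IL-15",
         stoich = c(IEL = -1, aIEL = 1),
         rate = if (patient)
           quote(k_act_iel * IEL * IL15^h_act_iel /
                   (K_act_iel^h_act_iel + IL15^h_act_iel))
         else 0),
    list(id = "iel_death", fig = 12L,
         label = "resting IEL death",
         stoich = c(IEL = -1),
         rate = quote(kd_iel * IEL)),
    list(id = "gluten_transport", fig = 13L,
         label = "gluten transport lumen -> lamina (zonulin + IEC deficit)",
         stoich = c(Glut_lum = -1, Glut_lam = 1),
         rate = quote((kz_transport * Zon +
                         ki_transport * max(0, 1 - IEC / IEC_healthy)) *
                        Glut_lum)),
    list(id = "glut_lam_degradation", fig = 14L,
         label = "lamina native peptide degradation",
         stoich = c(Glut_lam = -1),
         rate = quote(kdeg_glam * Glut_lam)),
    list(id = "dglut_degradation", fig = 15L,
         label = "deamidated peptide degradation",
         stoich = c(dGlut = -1),
         rate = quote(kdeg_dglut * dGlut))
  )

  if (patient) {
    rx <- c(rx, list(
      list(id = "apc_differentiation", fig = 16L,
           label = "APC differentiation from monocytes (IL-15 driven)",
           stoich = c(APC = 1),
           rate = quote(k_apc_basal +
                          k_apc_il15 * IL15 / (K_apc_il15 + IL15))),
      list(id = "apc_death", fig = 17L,
           label = "resting APC death",
           stoich = c(APC = -1),
           rate = quote(kd_apc * APC)),
      list(id = "apc_activation", fig = 18L,
           label = "APC activation by native + deamidated peptides",
           stoich = c(APC = -1, aAPC = 1),
           rate = quote(k_act_apc * APC *
                          (Glut_lam / (EC50_nat + Glut_lam) +
                             dGlut / (EC50_deam + dGlut)))),
      list(id = "aapc_death", fig = 19L,
           label = "activated APC death",
           stoich = c(aAPC = -1),
           rate = quote(kd_aapc * aAPC))
    ))
  }

  rx <- c(rx, list(
    list(id = "tcell_supply", fig = 20L,
         label = "T-cell supply into the lamina propria",
         stoich = c(Tcell = 1),
         rate = quote(s_tcell + 0)),
    list(id = "tcell_death", fig = 21L,
         label = "resting T-cell death",
         stoich = c(Tcell = -1),
         rate = quote(kd_tcell * Tcell)),
    list(id = "tcell_activation", fig = 22L,
         label = "T-cell activation by activated APC (IF-21 boosted)",
         stoich = c(Tcell = -1, aTt = 1),
         rate = if (patient)
           quote(k_act_t * Tcell * aAPC *
                   (1 + a_if21_t * IF21 / (K_if21_t + IF21)))
         else 0),
    list(id = "if21_synthesis", fig = 23L,
         label = "IF-21 synthesis by activated T cells and IEL",
         stoich = c(IF21 = 1),
         rate = quote(k_if21_at * aT + k_if21_aiel * aIEL)),
    list(id = "if21_degradation", fig = 24L,
         label = "IF-21 degradation",
         stoich = c(IF21 = -1),
         rate = quote(kdeg_if21 * IF21)),
    list(id = "ab_synthesis", fig = 25L,
         label = "antibody synthesis (aT + lamina peptides)",
         stoich = c(Ab = 1),
         rate = quote(ksab * aT * (Glut_lam + dGlut) /
                        (K_ab_pep + Glut_lam + dGlut))),
    list(id = "ab_degradation", fig = 26L,
         label = "antibody degradation",
         stoich = c(Ab = -1),
         rate = quote(kdeg_ab * Ab)),
    list(id = "zonulin_synthesis", fig = 31L,
         label = "zonulin synthesis by activated IEC",
         stoich = c(Zon = 1),
         rate = quote(k_zon * aIEC)),
    list(id = "zonulin_degradation", fig = 32L,
         label = "zonulin degradation",
         stoich = c(Zon = -1),
         rate = quote(kdeg_zon * Zon)),
    list(id = "deamidation", fig = 33L,
         label = "TG-2 deamidation of lamina peptides",
         stoich = c(Glut_lam = -1, dGlut = 1),
         rate = quote(kcat_deam * TG2_level * Glut_lam)),
    list(id = "tcell_transition", fig = 34L,
         label = "transient -> activated T cells",
         stoich = c(aTt = -1, aT = 1),
         rate = quote(k_trans_t * aTt)),
    list(id = "att_death", fig = 35L,
         label = "transient activated T-cell death",
         stoich = c(aTt = -1),
         rate = quote(kd_att * aTt)),
    list(id = "at_death", fig = 36L,
         label = "activated T-cell death",
         stoich = c(aT = -1),
         rate = quote(kd_at * aT))
  ))
  rx
}

#' Evaluate all reaction rates at a state
#'
#' @param net A `cd_network`.
#' @param state Named non-negative state vector over `net$species`.
#' @return Named numeric vector of reaction rates (one per reaction, all
#'   non-negative).
#' @export
reaction_rates <- function(net, state) {
  state <- check_state(net, state)
  v <- net$rate_fun(state)
  names(v) <- net$reactions$id
  v
}

#' ODE right-hand side
#'
#' Computes `dx/dt = N v(x)` for the network.
#'
#' @param net A `cd_network`.
#' @param state Named non-negative state vector.
#' @param t Time (unused; the system is autonomous, diet changes are handled
#'   by segment-wise simulation).
#' @return Named derivative vector.
#' @export
rhs <- function(net, state, t = 0) {
  state <- check_state(net, state)
  v <- net$rate_fun(state)
  drop(net$N %*% v)
}

check_state <- function(net, state) {
  if (is.null(names(state))) {
    if (length(state) != length(net$species)) {
      abort(paste0("state has ", length(state), " components; network has ",
                   length(net$species), " species"))
    }
    names(state) <- net$species
  } else {
    missing_sp <- setdiff(net$species, names(state))
    if (length(missing_sp) > 0) {
      abort(paste0("state lacks species: ",
                   paste(missing_sp, collapse = ", ")))
    }
    state <- state[net$species]
  }
  if (any(state < 0)) {
    abort(paste0("negative state component(s): ",
                 paste(names(state)[state < 0], collapse = ", ")))
  }
  state
}

#' @export
print.cd_network <- function(x, ...) {
  cat("<cd_network> ", x$variant, " variant, diet = ",
      if (is.numeric(x$diet)) format(x$diet) else x$diet, "\n", sep = "")
  cat("  ", length(x$species), " species, ", nrow(x$reactions),
      " reactions\n", sep = "")
  invisible(x)
}
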