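#' Calibration dataset
#'
#' A calibration dataset is a tibble of observations with columns
#' `observable`, `condition`, `value`, `weight` and `bound`. Observables are
#' `"antibody_pct"`, `"villous_area_pct"`, a species name (steady-state
#' level), or a transient diagnostic (`"t_ab_below_5"`, `"t_ab_above_10"`,
#' in days after the diet switch). Conditions are `"healthy"`,
#' `"patient_gluten"`, `"patient_gfd"`, `"switch_gluten_to_gfd"`,
#' `"switch_gfd_to_gluten"`, or `"intervention:<kind>:<strength>"`.
#'
#' `bound` is `"eq"` for an ordinary least-squares observation, or
#' `"le"`/`"ge"` for a one-sided constraint (the residual is the amount by
#' which the prediction violates the bound); one-sided terms express the
#' published transient-time and background-antibody constraints.
#'
#' @param observable,condition,value Observation descriptors (recycled to a
#'   common length).
#' @param weight Positive weights (default: `1/max(value, 1)^2`, i.e.
#'   relative error).
#' @param bound `"eq"`, `"le"` or `"ge"`.
#' @return A `cd_dataset` tibble.
#' @export
calibration_dataset <- function(observable, condition, value,
                                weight = NULL, bound = "eq") {
  tab <- tibble(observable = observable, condition = condition,
                value = as.numeric(value), bound = bound)
  if (is.null(weight)) {
    tab$weight <- 1 / pmax(abs(tab$value), 1)^2
  } else {
    tab$weight <- weight
  }
  if (any(tab$weight <= 0)) abort("weights must be > 0")
  bad <- setdiff(tab$bound, c("eq", "le", "ge"))
  if (length(bad) > 0) abort(paste0("unknown bound type: ", bad[1]))
  class(tab) <- unique(c("cd_dataset", class(tab)))
  tab
}

#' The published calibration anchors
#'
#' The quantitative anchors available for this model in the primary
#' literature: villous area of 100% (healthy), 50% (patient on gluten-free
#' diet) and 10% (patient on gluten diet); antibody level of 100% on a
#' gluten diet (the normalization identity) and below 5% on a gluten-free
#' diet; antibody decay below 5% within 90 days of a gluten-to-GFD switch;
#' antibody rise above 10% within 14 days of a GFD-to-gluten switch.
#'
#' @return A `cd_dataset` tibble.
#' @export
cd_constraint_dataset <- function() {
  calibration_dataset(
    observable = c("villous_area_pct", "villous_area_pct",
                   "villous_area_pct", "antibody_pct", "antibody_pct",
                   "t_ab_below_5", "t_ab_above_10"),
    condition = c("healthy", "patient_gfd", "patient_gluten",
                  "patient_gluten", "patient_gfd",
                  "switch_gluten_to_gfd", "switch_gfd_to_gluten"),
    value = c(100, 50, 10, 100, 5, 90, 14),
    bound = c("eq", "eq", "eq", "eq", "le", "le", "le")
  )
}

#' Model predictions for a calibration dataset
#'
#' @param params A [cd_parameters()] table.
#' @param dataset A [calibration_dataset()].
#' @param refs Optional precomputed [cd_references()].
#' @return Numeric vector of predictions, one per observation row.
#' @export
predict_observations <- function(params, dataset, refs = NULL) {
  if (is.null(refs)) refs <- cd_references(params)
  horizon_decay <- 200
  horizon_rise <- 90
  cache <- new.env(parent = emptyenv())

  switch_time <- function(which_switch, diagnostic) {
    key <- which_switch
    if (!is.null(cache[[key]])) {
      tr <- cache[[key]]
    } else {
      if (which_switch == "switch_gluten_to_gfd") {
        net <- build_network(params, "patient", diet = "gfd")
        tr <- simulate_model(net, refs$x_gluten,
                             seq(0, horizon_decay, by = 0.5))
      } else {
        net <- build_network(params, "patient", diet = "gluten")
        tr <- simulate_model(net, refs$x_gfd,
                             seq(0, horizon_rise, by = 0.25))
      }
      cache[[key]] <- tr
    }
    ab_pct <- 100 * tr$Ab / refs$ref_ab
    if (diagnostic == "t_ab_below_5") {
      i <- which(ab_pct < 5)[1]
    } else {
      i <- which(ab_pct > 10)[1]
    }
    if (is.na(i)) max(tr$time) * 2 else tr$time[i]
  }

  endpoint <- function(condition) {
    if (!is.null(cache[[condition]])) return(cache[[condition]])
    parts <- strsplit(condition, ":", fixed = TRUE)[[1]]
    ep <- intervention_endpoint(params, parts[2], as.numeric(parts[3]),
                                refs = refs)
    cache[[condition]] <- ep
    ep
  }

  state_of <- function(condition) {
    switch(condition,
           healthy = refs$x_healthy,
           patient_gluten = refs$x_gluten,
           patient_gfd = refs$x_gfd,
           abort(paste0("unknown condition: ", condition)))
  }

  vapply(seq_len(nrow(dataset)), function(i) {
    obs <- dataset$observable[i]
    cond <- dataset$condition[i]
    if (obs %in% c("t_ab_below_5", "t_ab_above_10")) {
      return(switch_time(cond, obs))
    }
    if (startsWith(cond, "intervention:")) {
      ep <- endpoint(cond)
      return(ep[[obs]])
    }
    x <- state_of(cond)
    if (obs == "antibody_pct") {
      return(100 * x[["Ab"]] / refs$ref_ab)
    }
    if (obs == "villous_area_pct") {
      return(100 * x[["IEC"]] / refs$ref_iec)
    }
    if (obs %in% names(x)) return(x[[obs]])
    abort(paste0("unresolvable observable: ", obs))
  }, numeric(1))
}

#' Define a fitting problem
#'
#' @param dataset A [calibration_dataset()].
#' @param params Full parameter table providing the fixed values and the
#'   starting point.
#' @param free Names of the free parameters (default: all `fitted`-tagged
#'   parameters).
#' @param lower,upper Named box bounds (defaults: start / 10 and start * 10).
#' @param step0,shrink,tol,max_iter Pattern-search settings (step in log10
#'   units).
#' @param predict Function `(params, dataset) -> numeric` giving the model
#'   prediction for every observation row; defaults to
#'   [predict_observations()] (the full disease model). Supplying a custom
#'   function lets the same fitting machinery run on reduced test models.
#' @return A `cd_fit_problem` list.
#' @export
fit_problem <- function(dataset, params, free = NULL,
                        lower = NULL, upper = NULL,
                        step0 = 0.25, shrink = 0.5, tol = 1e-4,
                        max_iter = 10000, predict = predict_observations) {
  if (is.null(free)) free <- cd_fitted_names(params)
  unknown <- setdiff(free, params$name)
  if (length(unknown) > 0) {
    abort(paste0("free parameters not in the set: ",
                 paste(unknown, collapse = ", ")))
  }
  start <- setNames(params$value[match(free, params$name)], free)
  if (any(start <= 0)) {
    abort("free parameters must be positive (the search runs in log space)")
  }
  if (is.null(lower)) lower <- start / 10
  if (is.null(upper)) upper <- start * 10
  lower <- lower[free]; upper <- upper[free]
  if (any(lower >= upper)) abort("bounds must satisfy lower < upper")
  structure(list(dataset = dataset, params = params, free = free,
                 start = start, lower = lower, upper = upper,
                 predict = predict,
                 settings = list(step0 = step0, shrink = shrink, tol = tol,
                                 max_iter = max_iter)),
            class = "cd_fit_problem")
}

#' Weighted sum-of-squares objective
#'
#' `f = sum_i w_i (v_i - vbar_i)^2` over the observations, where `v_i` is
#' the model prediction under observation i's condition. One-sided
#' observations contribute only when violated. Simulation failures yield a
#' large finite penalty so the pattern search can move away.
#'
#' @param free_values Named (or problem-ordered) values of the free
#'   parameters, natural scale.
#' @param problem A [fit_problem()].
#' @return Scalar objective value.
#' @export
sse_objective <- function(free_values, problem) {
  p <- problem$params
  vals <- setNames(as.numeric(free_values), problem$free)
  for (nm in problem$free) {
    p$value[p$name == nm] <- vals[[nm]]
  }
  predict <- problem$predict %||% predict_observations
  pred <- tryCatch(predict(p, problem$dataset),
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) {
    return(1e8)
  }
  d <- problem$dataset
  resid <- pred - d$value
  resid[d$bound == "le"] <- pmax(resid[d$bound == "le"], 0)
  resid[d$bound == "ge"] <- pmin(resid[d$bound == "ge"], 0)
  sum(d$weight * resid^2)
}

#' Hooke-Jeeves pattern search
#'
#' Classic derivative-free minimization: exploratory coordinate moves from a
#' base point, followed by a pattern (acceleration) move through successful
#' bases; the step is shrunk when no exploratory move improves, and the
#' search stops when the step drops below `tol` or `max_iter` base
#' iterations are exhausted. Box bounds are respected by clipping moves.
#'
#' @param objective Function of a numeric vector returning a scalar.
#' @param x0 Starting point (must evaluate to a finite objective).
#' @param step0 Initial step size (scalar or per-coordinate).
#' @param shrink Step shrink factor in (0, 1).
#' @param tol Terminal step size.
#' @param max_iter Iteration cap.
#' @param lower,upper Box bounds.
#' @return List with `x_opt`, `f_opt`, `n_iter`, `n_eval`, `converged`, and
#'   `trace` (matrix of accepted base points with objective values).
#' @examples
#' hooke_jeeves(function(x) sum((x - 2)^2), c(0, 0))$x_opt
#' @export
hooke_jeeves <- function(objective, x0, step0 = 0.25, shrink = 0.5,
                         tol = 1e-4, max_iter = 10000,
                         lower = -Inf, upper = Inf) {
  stopifnot(step0 > 0, shrink > 0, shrink < 1, tol > 0)
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  clip <- function(x) pmin(pmax(x, lower), upper)
  x0 <- clip(x0)
  n_eval <- 0L
  fn <- function(x) {
    n_eval <<- n_eval + 1L
    objective(x)
  }
  f0 <- fn(x0)
  if (!is.finite(f0)) abort("objective is not finite at the starting point")

  explore <- function(base, fbase, step) {
    x <- base; fx <- fbase
    for (i in seq_len(n)) {
      for (s in c(step, -step)) {
        cand <- x
        cand[i] <- min(max(cand[i] + s, lower[i]), upper[i])
        if (cand[i] == x[i]) next
        fc <- fn(cand)
        if (fc < fx) {
          x <- cand; fx <- fc
          break
        }
      }
    }
    list(x = x, f = fx)
  }

  base <- x0; fbase <- f0
  step <- rep_len(step0, 1)
  trace <- list(c(base, f = fbase))
  iter <- 0L
  while (step > tol && iter < max_iter) {
    iter <- iter + 1L
    ex <- explore(base, fbase, step)
    if (ex$f < fbase) {
      ## pattern move: extrapolate through the improved point
      repeat {
        pattern <- clip(ex$x + (ex$x - base))
        base <- ex$x; fbase <- ex$f
        trace[[length(trace) + 1L]] <- c(base, f = fbase)
        fp <- fn(pattern)
        ex2 <- if (is.finite(fp) && fp < fbase) {
          explore(pattern, fp, step)
        } else {
          explore(base, fbase, step)
        }
        if (ex2$f < fbase) {
          ex <- ex2
        } else {
          break
        }
        if (iter >= max_iter) break
        iter <- iter + 1L
      }
    } else {
      step <- step * shrink
    }
  }
  trace_mat <- do.call(rbind, trace)
  list(x_opt = base, f_opt = fbase, n_iter = iter, n_eval = n_eval,
       converged = step <= tol, trace = trace_mat)
}

#' Fit free parameters by pattern search
#'
#' Minimizes [sse_objective()] over the free parameters of a
#' [fit_problem()] with [hooke_jeeves()], searching in log10 space (all
#' model parameters are positive and span decades).
#'
#' @param problem A [fit_problem()].
#' @return A `cd_fit` object; see [tidy.cd_fit()] and [glance.cd_fit()].
#' @export
fit_model <- function(problem) {
  stopifnot(inherits(problem, "cd_fit_problem"))
  if (length(problem$free) == 0) {
    f0 <- sse_objective(numeric(0), problem)
    return(structure(list(problem = problem,
                          estimate = numeric(0), sse = f0, sse_initial = f0,
                          n_iter = 0L, n_eval = 1L, converged = TRUE,
                          trace = NULL),
                     class = "cd_fit"))
  }
  x0 <- log10(problem$start)
  obj <- function(x) sse_objective(10^x, problem)
  s <- problem$settings
  res <- hooke_jeeves(obj, x0, step0 = s$step0, shrink = s$shrink,
                      tol = s$tol, max_iter = s$max_iter,
                      lower = log10(problem$lower),
                      upper = log10(problem$upper))
  est <- setNames(10^res$x_opt, problem$free)
  structure(list(problem = problem, estimate = est,
                 sse = res$f_opt, sse_initial = obj(x0),
                 n_iter = res$n_iter, n_eval = res$n_eval,
                 converged = res$converged, trace = res$trace),
            class = "cd_fit")
}

#' Parameter table with fitted values substituted
#'
#' @param fit A `cd_fit`.
#' @return The problem's parameter table with the optimal free values.
#' @export
fitted_parameters <- function(fit) {
  p <- fit$problem$params
  for (nm in names(fit$estimate)) {
    p$value[p$name == nm] <- fit$estimate[[nm]]
  }
  p
}

#' Profile-likelihood confidence intervals
#'
#' For each free parameter the interval is the range over which the profile
#' objective stays below `SSE_min * (1 + qf(level, 1, n - p) / (n - p))`
#' (the standard F-based least-squares threshold), with the remaining free
#' parameters re-optimized at every profile point by a short pattern
#' search. Endpoints that run into the box bounds are reported at the bound
#' and flagged.
#'
#' @param problem A [fit_problem()].
#' @param fit The converged `cd_fit` for that problem.
#' @param level Confidence level (default 0.95).
#' @param n_profile Profile resolution per side (default 8 bisection steps).
#' @param re_optimize Re-optimize the other free parameters at each profile
#'   point (the default); turning this off gives fixed-parameter profiles.
#' @return Tibble with `name`, `estimate`, `ci_lo`, `ci_hi`, `at_bound`.
#' @export
confidence_intervals <- function(problem, fit, level = 0.95,
                                 n_profile = 8, re_optimize = TRUE) {
  free <- problem$free
  n_obs <- nrow(problem$dataset)
  p_free <- length(free)
  dof <- max(n_obs - p_free, 1)
  threshold <- fit$sse * (1 + qf(level, 1, dof) / dof) + 1e-12

  profile_sse <- function(nm, val) {
    others <- setdiff(free, nm)
    sub_params <- fit$problem$params
    sub_params$value[match(nm, sub_params$name)] <- val
    if (length(others) == 0 || !re_optimize) {
      vals <- fit$estimate
      vals[nm] <- val
      return(sse_objective(vals[free], problem))
    }
    sub_prob <- fit_problem(problem$dataset, sub_params, free = others,
                            lower = problem$lower[others],
                            upper = problem$upper[others],
                            step0 = 0.05, shrink = 0.5, tol = 0.004,
                            max_iter = 120,
                            predict = problem$predict %||% predict_observations)
    sub_prob$start <- fit$estimate[others]
    fit_model(sub_prob)$sse
  }

  rows <- purrr::map_dfr(free, function(nm) {
    est <- fit$estimate[[nm]]
    lo_bound <- problem$lower[[nm]]
    hi_bound <- problem$upper[[nm]]
    find_edge <- function(direction) {
      bound <- if (direction < 0) lo_bound else hi_bound
      ## step outward in log space until the threshold is crossed
      inside <- est
      outside <- NULL
      for (fac in 2^(seq_len(12) / 2)) {
        cand <- if (direction < 0) est / fac else est * fac
        cand <- if (direction < 0) max(cand, bound) else min(cand, bound)
        if (profile_sse(nm, cand) > threshold) {
          outside <- cand
          break
        }
        inside <- cand
        if (cand == bound) break
      }
      if (is.null(outside)) {
        return(list(edge = bound, at_bound = TRUE))
      }
      for (i in seq_len(n_profile)) {
        mid <- sqrt(inside * outside)
        if (profile_sse(nm, mid) > threshold) outside <- mid else inside <- mid
      }
      list(edge = sqrt(inside * outside), at_bound = FALSE)
    }
    lo <- find_edge(-1)
    hi <- find_edge(1)
    tibble(name = nm, estimate = est,
           ci_lo = min(lo$edge, est), ci_hi = max(hi$edge, est),
           at_bound = lo$at_bound || hi$at_bound)
  })
  rows
}

#' Generate synthetic observations from a known parameter set
#'
#' Simulates each requested observation at the supplied parameters and
#' perturbs it with multiplicative lognormal noise of the given coefficient
#' of variation. Used for parameter-recovery and coverage testing.
#'
#' @param true_params Parameter table regarded as the truth.
#' @param design A tibble with `observable` and `condition` columns (e.g. a
#'   [cd_constraint_dataset()] stripped of values).
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param seed Integer seed.
#' @return A [calibration_dataset()] with noisy values, all `"eq"` bounds.
#' @export
synth_observations <- function(true_params, design, noise_cv = 0.1,
                               seed = 1) {
  stopifnot(noise_cv >= 0)
  base <- calibration_dataset(design$observable, design$condition,
                              value = 0, weight = rep(1, nrow(design)))
  truth <- predict_observations(true_params, base)
  set.seed(seed)
  noisy <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    truth * exp(rnorm(length(truth), mean = -sdlog^2 / 2, sd = sdlog))
  } else {
    truth
  }
  calibration_dataset(design$observable, design$condition, value = noisy,
                      weight = rep(1, nrow(design)))
}
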