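#' Simulate the model
#'
#' Integrates `dx/dt = N v(x)` with a stiff-capable solver
#' ([deSolve::ode()], `lsoda`). States are clipped at zero inside the
#' right-hand side (all rate laws vanish with their substrates, so the flow
#' is non-negativity preserving; the clip only guards solver round-off).
#'
#' @param net A `cd_network`.
#' @param x0 Named non-negative initial state.
#' @param t_grid Strictly increasing time grid in days.
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @param ... Passed to [deSolve::ode()].
#' @return A `cd_trajectory` tibble: `time` plus one column per species.
#'   Attributes carry the network variant and parameters.
#' @examples
#' net <- build_network(cd_parameters(), "healthy")
#' tr <- simulate_model(net, cd_initial_state(cd_parameters(), "healthy"),
#'                      seq(0, 10, by = 1))
#' @export
simulate_model <- function(net, x0, t_grid, rtol = 1e-8, atol = 1e-10, ...) {
  x0 <- check_state(net, x0)
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    abort("t_grid must be strictly increasing with at least two points")
  }
  f <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(drop(net$N %*% net$rate_fun(y)))
  }
  out <- deSolve::ode(y = x0, times = t_grid, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000, ...)
  if (attr(out, "istate")[1] < 0) {
    last <- out[nrow(out), ]
    abort(paste0("integration failed at t = ", format(last[["time"]]),
                 " (last good state attached)"),
          class = "cd_integration_error", last_state = last)
  }
  tr <- as_tibble(as.data.frame(unclass(out)))
  for (sp in net$species) tr[[sp]] <- pmax(tr[[sp]], 0)
  attr(tr, "variant") <- net$variant
  attr(tr, "diet") <- net$diet
  attr(tr, "params") <- net$params
  class(tr) <- unique(c("cd_trajectory", class(tr)))
  tr
}

#' Solve for a steady state
#'
#' Damped Newton iteration on the right-hand side with a numerical Jacobian,
#' falling back to long integration (followed by a Newton polish) when the
#' iteration stalls or leaves the non-negative orthant. The convergence test
#' is per species, relative to the total flux through that species, so fast
#' and slow species are judged on their own scales.
#'
#' @param net A `cd_network`.
#' @param x_guess Named non-negative starting state. Defaults to
#'   [cd_initial_state()] for the network's parameters.
#' @param tol Relative residual tolerance (default 1e-10).
#' @param max_iter Maximum Newton iterations per attempt.
#' @return Named steady-state vector with attribute `converged`.
#' @export
steady_state <- function(net, x_guess = NULL, tol = 1e-10, max_iter = 100) {
  if (is.null(x_guess)) {
    x_guess <- cd_initial_state(net$params, net$variant)
  }
  x_guess <- check_state(net, x_guess)

  x <- newton_steady(net, x_guess, tol, max_iter)
  if (is.null(x)) {
    ## integrate towards the attractor, then polish
    end <- run_to_rest(net, x_guess)
    x <- newton_steady(net, end, tol, max_iter)
    if (is.null(x)) {
      x <- structure(end, converged = FALSE)
      warn("steady_state: Newton did not converge; returning long-integration endpoint")
      return(x)
    }
  }
  structure(x, converged = TRUE)
}

# One damped-Newton attempt; NULL if it fails.
newton_steady <- function(net, x0, tol, max_iter) {
  n <- length(x0)
  Nabs <- abs(net$N)
  f <- function(x) drop(net$N %*% net$rate_fun(pmax(x, 0)))
  scale_of <- function(x) pmax(drop(Nabs %*% net$rate_fun(pmax(x, 0))), 1e-8)
  x <- pmax(x0, 0)
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    if (all(abs(fx) <= tol * scale_of(x) + 1e-13)) {
      return(setNames(pmax(x, 0), net$species))
    }
    J <- tryCatch(pracma::jacobian(f, x), error = function(e) NULL)
    if (is.null(J) || any(!is.finite(J))) return(NULL)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    ok <- FALSE
    for (lam in 2^-(0:8)) {
      x_new <- x + lam * step
      if (min(x_new) < -1e-8 * max(abs(x), 1)) next
      x_new <- pmax(x_new, 0)
      f_new <- f(x_new)
      if (sum(f_new^2) < sum(fx^2) || lam == 2^-8) {
        x <- x_new
        fx <- f_new
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  if (all(abs(fx) <= 1e2 * tol * scale_of(x) + 1e-12)) {
    return(setNames(pmax(x, 0), net$species))
  }
  NULL
}

# Integrate until the state stops moving (used as Newton fallback and as the
# independent long-run check of steady states).
run_to_rest <- function(net, x0, t_max = 4000, chunk = 500) {
  x <- pmax(x0, 0)
  t_done <- 0
  while (t_done < t_max) {
    tr <- tryCatch(
      simulate_model(net, x, seq(0, chunk, length.out = 51),
                     rtol = 1e-9, atol = 1e-11),
      cd_integration_error = function(e) NULL)
    if (is.null(tr)) {
      ## retry the chunk with a laxer tolerance before giving up
      tr <- simulate_model(net, x, seq(0, chunk, length.out = 51),
                           rtol = 1e-6, atol = 1e-9)
    }
    x_new <- unlist(tr[nrow(tr), net$species])
    rel <- max(abs(x_new - x) / pmax(abs(x_new), 1e-8))
    x <- x_new
    t_done <- t_done + chunk
    if (rel < 1e-9) break
  }
  setNames(x, net$species)
}
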