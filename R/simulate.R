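#' @title Time-course integration and steady states
#' @name simulate
#' @description Deterministic integration of a [ga_model()] with a
#'   stiff-capable solver, and certified steady-state computation by
#'   integrate-then-polish.
NULL

.SIM_DEFAULTS <- list(rel_tol = 1e-8, abs_tol = 1e-10,
                      ss_tol = 1e-8, t_max = 5000,
                      diverge_bound = 1e8)

#' Wrap an arbitrary ODE right-hand side as a model
#'
#' The integration and steady-state machinery works for any model
#' definition, not only the GA network: this constructor wraps a plain
#' derivative function and a species roster into the same `"ga_model"`
#' interface.  Used for reduced and analytic test systems.
#'
#' @param rhs Function `(state, t)` returning the derivative vector.
#' @param species Character vector naming the state entries.
#' @return A `"ga_model"` object with a custom RHS.
#' @export
#' @examples
#' relax <- ode_model(function(s, t) c(x = 2 - 4 * s[["x"]]), "x")
#' find_steady_state(relax, init = c(x = 0))$state   # a/b = 0.5
ode_model <- function(rhs, species) {
  stopifnot(is.function(rhs), is.character(species), length(species) >= 1)
  structure(list(species = species, rhs_fn = rhs),
            class = "ga_model")
}

model_rhs <- function(model, state, t = 0) {
  if (!is.null(model$rhs_fn)) {
    d <- model$rhs_fn(state, t)
    if (any(!is.finite(d)))
      stop("non-finite derivative", call. = FALSE)
    d
  } else {
    ga_rhs(state, t, model)
  }
}

#' Default numerical settings
#'
#' Integrator relative/absolute tolerances, the steady-state residual
#' tolerance, the default steady-state horizon and the divergence bound.
#' All overridable per call.
#'
#' @return Named list.
#' @export
sim_defaults <- function() .SIM_DEFAULTS

#' Integrate a model over a time grid
#'
#' Solves the initial-value problem with `deSolve`'s `lsoda` (automatic
#' stiff/non-stiff switching).  Negative excursions beyond `-abs_tol` are
#' clipped to zero with a warning; smaller excursions are clipped silently
#' (they are within the solver's own error tolerance).
#'
#' @param model A [ga_model()].
#' @param init Named non-negative initial state over [ga_species()];
#'   defaults to [initial_state()].
#' @param times Strictly increasing numeric time grid.
#' @param rel_tol,abs_tol Solver tolerances.
#' @return Object of class `"ga_trajectory"`: list with `times`, `state`
#'   (matrix, time x species), `model`, and `diagnostics` (tolerances,
#'   number of clipped entries).
#' @export
#' @examples
#' m <- ga_model(default_parameters(), "wildtype")
#' tr <- integrate_model(m, times = seq(0, 10, by = 1))
#' tr$state[nrow(tr$state), "GA4"]
integrate_model <- function(model, init = initial_state(model),
                            times,
                            rel_tol = .SIM_DEFAULTS$rel_tol,
                            abs_tol = .SIM_DEFAULTS$abs_tol) {
  stopifnot(inherits(model, "ga_model"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 points",
         call. = FALSE)
  init <- check_state(init, model$species)
  func <- function(t, y, parms) {
    names(y) <- model$species
    list(unname(model_rhs(model, y, t)))
  }
  sol <- deSolve::lsoda(y = unname(init), times = times, func = func,
                        parms = NULL, rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1L] < 0) {
    last <- max(sol[, 1L])
    stop("integration failed at t = ", format(last),
         " (last good time point)", call. = FALSE)
  }
  state <- sol[, -1L, drop = FALSE]
  colnames(state) <- model$species
  deep <- state < -abs_tol
  if (any(deep))
    warning(sum(deep), " state value(s) below -abs_tol clipped to 0",
            call. = FALSE)
  n_clip <- sum(state < 0)
  state[state < 0] <- 0
  structure(list(times = sol[, 1L], state = state, model = model,
                 diagnostics = list(rel_tol = rel_tol, abs_tol = abs_tol,
                                    n_clipped = n_clip,
                                    n_steps = attr(sol, "istate")[3L])),
            class = "ga_trajectory")
}

#' @export
print.ga_trajectory <- function(x, ...) {
  cat("GA trajectory:", length(x$times), "time points x",
      ncol(x$state), "species, t in [",
      x$times[1L], ",", x$times[length(x$times)], "]\n")
  invisible(x)
}

check_state <- function(init, species = .GA_SPECIES) {
  if (is.null(names(init))) {
    if (length(init) != length(species))
      stop("unnamed init must have ", length(species), " entries",
           call. = FALSE)
    names(init) <- species
  } else {
    unknown <- setdiff(names(init), species)
    if (length(unknown))
      stop("unknown species in init: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    full <- stats::setNames(numeric(length(species)), species)
    full[names(init)] <- init
    init <- full
  }
  if (any(!is.finite(init)) || any(init < 0))
    stop("init must be finite and non-negative", call. = FALSE)
  init
}

#' Sup-norm of the model derivative at a state
#'
#' Zero exactly at an equilibrium of the RHS; used to certify steady states.
#'
#' @param model A [ga_model()].
#' @param state Named state vector.
#' @return `max(abs(ga_rhs(state)))`.
#' @export
residual_norm <- function(model, state) {
  max(abs(model_rhs(model, check_state(state, model$species), 0)))
}

#' Find a steady state by integrate-then-polish
#'
#' Integrates from `init` in geometrically growing chunks, checking the
#' residual norm after each; once the residual is small (or the horizon
#' `t_max` is reached) the endpoint seeds a damped Levenberg-Marquardt
#' root-polish of the RHS.  A polished root is accepted only if it is
#' non-negative and its residual is below `tol`; otherwise the integration
#' endpoint is reported, with `converged = FALSE` if it too fails the
#' residual bound.  Divergence (state norm above `diverge_bound`) yields a
#' non-converged result rather than an error, so parameter sweeps never
#' abort.
#'
#' @inheritParams integrate_model
#' @param tol Residual tolerance certifying the equilibrium.
#' @param t_max Integration horizon.
#' @param polish If `FALSE`, pure integration (no root step); used for
#'   cross-validating the two routes.
#' @param diverge_bound State sup-norm beyond which the run is declared
#'   divergent.
#' @return Object of class `"ga_steady_state"`: list with `state`,
#'   `converged`, `residual`, `method` (`"integration"` or `"root"`),
#'   `t_used`.
#' @export
#' @examples
#' m <- ga_model(default_parameters(), "gahacr")
#' ss <- find_steady_state(m)
#' ss$converged
#' ss$state[["GA4"]]
find_steady_state <- function(model, init = initial_state(model),
                              tol = .SIM_DEFAULTS$ss_tol,
                              t_max = .SIM_DEFAULTS$t_max,
                              rel_tol = .SIM_DEFAULTS$rel_tol,
                              abs_tol = .SIM_DEFAULTS$abs_tol,
                              polish = TRUE,
                              diverge_bound = .SIM_DEFAULTS$diverge_bound) {
  stopifnot(inherits(model, "ga_model"))
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  x <- check_state(init, model$species)
  t_now <- 0
  chunk <- 25
  res <- residual_norm(model, x)
  # coarse pre-tolerance under which polishing is attempted early; the
  # transient only has to reach the root-finder's basin, so it may be
  # integrated at relaxed tolerance — the certificate is the residual
  # bound on the polished root, not the transient's accuracy
  pre_tol <- max(tol, 1e-2)
  pre_rel <- if (polish) max(rel_tol, 1e-6) else rel_tol
  pre_abs <- if (polish) max(abs_tol, 1e-9) else abs_tol
  while (res >= tol && t_now < t_max) {
    step <- min(chunk, t_max - t_now)
    tr <- tryCatch(
      suppressWarnings(integrate_model(model, init = x,
                                       times = c(0, step),
                                       rel_tol = pre_rel,
                                       abs_tol = pre_abs)),
      error = function(e) NULL)
    if (is.null(tr))
      return(steady_result(x, FALSE, res, "integration", t_now,
                           model$species))
    x <- tr$state[nrow(tr$state), ]
    t_now <- t_now + step
    if (max(abs(x)) > diverge_bound)
      return(steady_result(x, FALSE, Inf, "integration", t_now,
                           model$species))
    res <- residual_norm(model, x)
    if (polish && res < pre_tol) break
    chunk <- min(chunk * 2, 400)
  }
  if (polish) {
    polished <- polish_root(model, x)
    if (!is.null(polished)) {
      pres <- residual_norm(model, polished)
      # accept only a certified root close to the integration endpoint
      # (guards against the polish jumping to a different branch)
      near <- max(abs(polished - x)) <= 0.25 * max(1, max(abs(x)))
      if (pres < tol && pres <= res && near)
        return(steady_result(polished, TRUE, pres, "root", t_now,
                             model$species))
    }
    # polish failed: fall back to accurate integration to the horizon
    while (res >= tol && t_now < t_max) {
      step <- min(chunk, t_max - t_now)
      tr <- tryCatch(
        suppressWarnings(integrate_model(model, init = x,
                                         times = c(0, step),
                                         rel_tol = rel_tol,
                                         abs_tol = abs_tol)),
        error = function(e) NULL)
      if (is.null(tr))
        return(steady_result(x, FALSE, res, "integration", t_now,
                             model$species))
      x <- tr$state[nrow(tr$state), ]
      t_now <- t_now + step
      if (max(abs(x)) > diverge_bound)
        return(steady_result(x, FALSE, Inf, "integration", t_now,
                             model$species))
      res <- residual_norm(model, x)
      chunk <- min(chunk * 2, 400)
    }
  }
  steady_result(x, res < tol, res, "integration", t_now, model$species)
}

steady_result <- function(state, converged, residual, method, t_used,
                          species) {
  names(state) <- species
  structure(list(state = state, converged = converged,
                 residual = residual, method = method, t_used = t_used),
            class = "ga_steady_state")
}

#' @export
print.ga_steady_state <- function(x, ...) {
  cat("GA steady state (", x$method, "): converged = ", x$converged,
      ", ||rhs||_inf = ", format(x$residual, digits = 3),
      ", GA4 = ", format(x$state[["GA4"]], digits = 6), "\n", sep = "")
  invisible(x)
}

# Levenberg-Marquardt root polish of the RHS, seeded at `x0`.  Returns the
# root (clipped at tiny negatives) or NULL on failure / inadmissible root.
polish_root <- function(model, x0) {
  fn <- function(y) {
    y <- pmax(y, 0)
    names(y) <- model$species
    unname(model_rhs(model, y, 0))
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = unname(x0), fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  root <- out$par
  if (any(!is.finite(root)) || any(root < -1e-8)) return(NULL)
  pmax(root, 0)
}
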