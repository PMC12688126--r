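#' @title Parameter sweeps and variant comparisons
#' @name sweep
#' @description Steady-state GA4 surfaces over two-parameter grids, the
#'   three-variant time-course comparison, and the derived readouts
#'   (relative reduction, nonlinearity score) used to contrast the closed-
#'   and open-loop repressors.
NULL

#' Define a sweep axis over one parameter
#'
#' @param name Parameter name; must exist in [ga_parameter_names()].
#' @param values Strictly increasing numeric values.
#' @param scale `"linear"` or `"log"`, a display/metadata tag.
#' @return Object of class `"parameter_axis"`.
#' @export
#' @examples
#' parameter_axis("hacr_repstr", c(0.1, 1, 10))
parameter_axis <- function(name, values, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!name %in% ga_parameter_names())
    stop("unknown parameter for axis: ", name, call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)) ||
      any(diff(values) <= 0))
    stop("axis values must be finite and strictly increasing",
         call. = FALSE)
  structure(list(name = name, values = values, scale = scale),
            class = "parameter_axis")
}

#' Two-parameter steady-state sweep
#'
#' Computes the steady-state readout (default GA4) of a regulatory variant
#' on the outer grid of two parameter axes.  Each cell overrides the two
#' axis parameters on the (pre-variant) base set, applies the variant, and
#' runs [find_steady_state()].  Along each row the search warm-starts from
#' the previous cell's solution — the surface is continuous in the
#' parameters, so the neighboring equilibrium is an excellent seed — and
#' falls back to the rest state when that fails.  Unconverged cells carry
#' `NA`, never a silent number.  The computation is deterministic.
#'
#' @param params Base [ga_parameters()] set (pre-variant).
#' @param variant A [variant_spec()] or variant name.
#' @param axis_x,axis_y [parameter_axis()] objects over distinct parameters.
#' @param readout Species whose steady-state value fills the matrix.
#' @param ... Passed on to [find_steady_state()] (tolerances, `t_max`).
#' @return Object of class `"ga_sweep"`: list with `axis_x`, `axis_y`,
#'   `readout`, `values` (matrix |y| x |x|), `converged` (logical matrix),
#'   `residuals`, `variant`.
#' @export
#' @examples
#' sw <- sweep_2d(default_parameters(), "gahacr",
#'                parameter_axis("hacr_repstr", c(0.1, 10)),
#'                parameter_axis("hacr_ga_decay", c(0.5, 50)))
#' sw$values
sweep_2d <- function(params, variant, axis_x, axis_y, readout = "GA4",
                     ...) {
  params <- ga_parameters(params)
  if (!inherits(variant, "variant_spec")) {
    variant <- if (identical(variant, "wildtype"))
      variant_spec("wildtype") else variant_spec(variant)
  }
  stopifnot(inherits(axis_x, "parameter_axis"),
            inherits(axis_y, "parameter_axis"))
  if (axis_x$name == axis_y$name)
    stop("sweep axes must reference distinct parameters", call. = FALSE)
  if (!readout %in% ga_species())
    stop("unknown readout species: ", readout, call. = FALSE)
  nx <- length(axis_x$values); ny <- length(axis_y$values)
  vals <- matrix(NA_real_, nrow = ny, ncol = nx)
  conv <- matrix(FALSE, nrow = ny, ncol = nx)
  resid <- matrix(NA_real_, nrow = ny, ncol = nx)
  dimnames(vals) <- dimnames(conv) <- dimnames(resid) <-
    list(format(axis_y$values, digits = 6),
         format(axis_x$values, digits = 6))
  for (j in seq_len(ny)) {
    warm <- NULL
    for (i in seq_len(nx)) {
      p <- params
      p[[axis_x$name]] <- axis_x$values[i]
      p[[axis_y$name]] <- axis_y$values[j]
      model <- ga_model(p, variant)
      ss <- NULL
      if (!is.null(warm))
        ss <- find_steady_state(model, init = warm, ...)
      if (is.null(ss) || !ss$converged)
        ss <- find_steady_state(model, ...)
      if (ss$converged) {
        vals[j, i] <- ss$state[[readout]]
        conv[j, i] <- TRUE
        resid[j, i] <- ss$residual
        warm <- ss$state
      } else {
        warm <- NULL
      }
    }
  }
  structure(list(axis_x = axis_x, axis_y = axis_y, readout = readout,
                 values = vals, converged = conv, residuals = resid,
                 variant = variant),
            class = "ga_sweep")
}

#' @export
print.ga_sweep <- function(x, ...) {
  cat("GA steady-state sweep (", x$variant$variant, "): ",
      x$axis_y$name, " x ", x$axis_x$name, " -> ", x$readout,
      ", ", sum(x$converged), "/", length(x$converged),
      " cells converged\n", sep = "")
  invisible(x)
}

#' Compare the three regulatory variants on one parameter set
#'
#' Runs the wildtype, no-degron repressor and GAHACR variants from the same
#' (pre-variant) parameters, the same initial state and the same time grid,
#' returning each variant's trajectory and steady state.
#'
#' @param params Base [ga_parameters()] set.
#' @param init Common initial state; default [initial_state()].
#' @param times Common time grid.
#' @param target Target transcription unit for the two repressor variants.
#' @param ... Passed to [integrate_model()] and [find_steady_state()]
#'   (tolerances).
#' @return Object of class `"ga_variant_comparison"`: list with `times`
#'   and, per variant, `trajectory` and `steady_state`.
#' @export
#' @examples
#' cmp <- compare_variants(default_parameters(), times = seq(0, 20, 1))
#' sapply(cmp$variants, function(v) v$steady_state$state[["GA4"]])
compare_variants <- function(params, init = initial_state(),
                             times = seq(0, 200, by = 0.5),
                             target = "GA20ox", ...) {
  params <- ga_parameters(params)
  out <- lapply(c(wildtype = "wildtype", no_degron_cr = "no_degron_cr",
                  gahacr = "gahacr"), function(v) {
    spec <- if (v == "wildtype") variant_spec("wildtype")
            else variant_spec(v, target)
    model <- ga_model(params, spec)
    list(trajectory = integrate_model(model, init = init, times = times,
                                      ...),
         steady_state = find_steady_state(model, init = init, ...))
  })
  structure(list(times = times, init = init, variants = out),
            class = "ga_variant_comparison")
}

#' @export
print.ga_variant_comparison <- function(x, ...) {
  ga4 <- vapply(x$variants,
                function(v) v$steady_state$state[["GA4"]], numeric(1))
  cat("Variant comparison — steady-state GA4:\n")
  print(signif(ga4, 6))
  invisible(x)
}

#' Fractional reduction of a sweep surface against a baseline
#'
#' `(baseline - cell) / baseline` per sweep cell: the fraction of the
#' unrepressed steady-state readout lost to repression.  Unconverged cells
#' stay `NA`.
#'
#' @param sweep A [sweep_2d()] result.
#' @param baseline A converged [find_steady_state()] result for the
#'   no-repressor reference (readout must be positive).
#' @return Numeric matrix shaped like `sweep$values`.
#' @export
relative_reduction <- function(sweep, baseline) {
  stopifnot(inherits(sweep, "ga_sweep"),
            inherits(baseline, "ga_steady_state"))
  if (!baseline$converged)
    stop("baseline steady state did not converge", call. = FALSE)
  b <- baseline$state[[sweep$readout]]
  if (!is.finite(b) || b <= 0)
    stop("baseline readout must be positive", call. = FALSE)
  (b - sweep$values) / b
}

#' Nonlinearity of a dose-response curve
#'
#' One minus the coefficient of determination (R^2) of the best straight
#' line through the ordered (parameter, readout) pairs: 0 for exactly
#' linear data, approaching 1 as the straight-line fit degrades.  Used to
#' contrast the GAHACR's feedback-shaped response with the open-loop
#' no-degron repressor's.
#'
#' @param x Parameter values, strictly increasing, length >= 4.
#' @param y Readout values, same length.
#' @return Dimensionless score in `[0, 1]`.
#' @export
#' @examples
#' nonlinearity_score(1:5, 2 * (1:5) + 1)   # 0: exactly linear
#' nonlinearity_score(seq(0, 1, 0.25), seq(0, 1, 0.25)^2)
nonlinearity_score <- function(x, y) {
  if (length(x) < 4L || length(y) != length(x))
    stop("need at least 4 (x, y) pairs of equal length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("x must be strictly increasing", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)  # constant curve: a straight line fits exactly
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  max(0, min(1, rss / tss))
}

#' Steady-state response to an expression-level ramp
#'
#' Convenience wrapper used by the nonlinearity contrast: steady-state
#' readout of one variant along a ramp of the repressor transcription rate
#' (`hacr_tx`, the promoter-strength knob) at fixed repression strength.
#'
#' @param params Base parameter set.
#' @param variant Variant name or [variant_spec()].
#' @param tx_values Strictly increasing `hacr_tx` values.
#' @param readout Readout species.
#' @param ... Passed to [find_steady_state()].
#' @return Data frame with columns `hacr_tx`, `readout`, `converged`.
#' @export
expression_ramp <- function(params, variant, tx_values, readout = "GA4",
                            ...) {
  params <- ga_parameters(params)
  axis <- parameter_axis("hacr_tx", tx_values)
  vals <- rep(NA_real_, length(tx_values))
  conv <- rep(FALSE, length(tx_values))
  warm <- NULL
  for (i in seq_along(tx_values)) {
    p <- params
    p[["hacr_tx"]] <- tx_values[i]
    model <- ga_model(p, variant)
    ss <- NULL
    if (!is.null(warm)) ss <- find_steady_state(model, init = warm, ...)
    if (is.null(ss) || !ss$converged) ss <- find_steady_state(model, ...)
    if (ss$converged) {
      vals[i] <- ss$state[[readout]]
      conv[i] <- TRUE
      warm <- ss$state
    } else warm <- NULL
  }
  data.frame(hacr_tx = tx_values, readout = vals, converged = conv)
}
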