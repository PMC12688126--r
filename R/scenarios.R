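#' @title Baseline constants, bundled scenarios, parameter ensembles
#' @name scenarios
#' @description The baseline parameter set, the three bundled modeling
#'   scenarios (variant dynamics and the two steady-state sweep surfaces),
#'   and a seeded log-normal parameter-perturbation harness for robustness
#'   analysis.
NULL

#' Baseline model parameter set
#'
#' Rate constants of the GA network in nondimensional units (time in hours,
#' concentrations scaled to order one).  Transcription, translation and
#' decay rates of the four endogenous transcription units share common
#' magnitudes (maximal transcription 1, mRNA half-life ~ 40 min, protein
#' half-life ~ 7 h); Hill thresholds sit at 0.5 with coefficient 2 so the
#' feedbacks operate on their sensitive flank; GA-induced DELLA degradation
#' is fast relative to basal decay.  The GAHACR block mimics DELLA
#' constant-for-constant (transcription, translation, mRNA and protein
#' decay, GA-induced degradation), and the repression strength defaults to
#' 1, the log-midpoint of the sweep range explored by
#' [figure1_scenarios()].
#'
#' @return A [ga_parameters()] set.
#' @export
#' @examples
#' p <- default_parameters()
#' p[["hacr_ga_decay"]] == p[["della_ga_decay"]]
default_parameters <- function() {
  ga_parameters(c(
    ga12_synthesis = 1, k_ga20ox = 1, k_ga3ox = 1,
    ga_turnover = 0.1, ga4_turnover = 0.2,
    k_bind = 1, k_unbind = 0.2, complex_turnover = 10,
    ga20ox_tx = 1, ga20ox_mrna_decay = 1, ga20ox_tl = 1,
    ga20ox_decay = 0.1, K_ga20ox = 0.5, n_ga20ox = 2,
    ga3ox_tx = 1, ga3ox_mrna_decay = 1, ga3ox_tl = 1,
    ga3ox_decay = 0.1, K_ga3ox = 0.5, n_ga3ox = 2,
    gid1_tx = 1, gid1_mrna_decay = 1, gid1_tl = 1,
    gid1_decay = 0.1, K_gid1 = 0.5, n_gid1 = 2,
    della_tx = 1, della_mrna_decay = 1, della_tl = 1,
    della_decay = 0.1, della_ga_decay = 5, K_della = 0.5, n_della = 2,
    hacr_tx = 1, hacr_tl = 1, hacr_mrna_decay = 1,
    hacr_protein_decay = 0.1, hacr_ga_decay = 5,
    hacr_repstr = 1, hacr_rep_exponent = 1
  ))
}

#' Bundled modeling scenarios
#'
#' The three scenarios exercised throughout the package:
#' \describe{
#'   \item{fig1D_dynamics}{time-course comparison of the wildtype,
#'     no-degron repressor and GAHACR variants from the common rest state.}
#'   \item{fig1E_sweep}{steady-state GA4 surface for the \emph{no-degron}
#'     repressor over repression strength x repressor degradation rate.}
#'   \item{fig1F_sweep}{the same surface for the \emph{GAHACR} variant.}
#' }
#' Sweep axes span two decades either side of the default value, 8
#' log-spaced points each.  Each scenario is fully self-describing and
#' round-trips through [write_scenario()] / [load_scenario()].
#'
#' @param params Base parameter set; default [default_parameters()].
#' @return Named list of three `"ga_scenario"` objects.
#' @export
#' @examples
#' names(figure1_scenarios())
figure1_scenarios <- function(params = default_parameters()) {
  params <- ga_parameters(params)
  axis_rep <- parameter_axis("hacr_repstr",
                             log_axis(params[["hacr_repstr"]], 8))
  axis_deg <- parameter_axis("hacr_ga_decay",
                             log_axis(params[["hacr_ga_decay"]], 8))
  list(
    fig1D_dynamics = ga_scenario(
      name = "fig1D_dynamics", kind = "compare",
      params = params, variant = variant_spec("gahacr", "GA20ox"),
      t_end = 200, t_step = 0.5, seed = 1L),
    fig1E_sweep = ga_scenario(
      name = "fig1E_sweep", kind = "sweep",
      params = params, variant = variant_spec("no_degron_cr", "GA20ox"),
      axis_x = axis_rep, axis_y = axis_deg, readout = "GA4", seed = 1L),
    fig1F_sweep = ga_scenario(
      name = "fig1F_sweep", kind = "sweep",
      params = params, variant = variant_spec("gahacr", "GA20ox"),
      axis_x = axis_rep, axis_y = axis_deg, readout = "GA4", seed = 1L)
  )
}

# 10^-2 .. 10^2 x `center`, n log-spaced points
log_axis <- function(center, n) {
  exp(seq(log(center * 1e-2), log(center * 1e2), length.out = n))
}

#' Construct a scenario
#'
#' A self-describing bundle of everything one run needs: a name, the
#' (pre-variant) parameter set, the regulatory variant, either a time grid
#' (`kind = "simulate"` or `"compare"`) or two sweep axes
#' (`kind = "sweep"`), and a seed.
#'
#' @param name Scenario name.
#' @param kind One of `"simulate"`, `"compare"`, `"steady"`, `"sweep"`.
#' @param params A [ga_parameters()] set.
#' @param variant A [variant_spec()].
#' @param t_end,t_step Time grid `seq(0, t_end, by = t_step)` for
#'   trajectory kinds.
#' @param axis_x,axis_y [parameter_axis()] objects for `kind = "sweep"`.
#' @param readout Readout species for sweeps (default `"GA4"`).
#' @param seed Integer seed recorded with the scenario.
#' @return Object of class `"ga_scenario"`.
#' @export
ga_scenario <- function(name, kind = c("simulate", "compare", "steady",
                                       "sweep"),
                        params = default_parameters(),
                        variant = variant_spec("gahacr"),
                        t_end = 200, t_step = 0.5,
                        axis_x = NULL, axis_y = NULL,
                        readout = "GA4", seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  params <- ga_parameters(params)
  stopifnot(inherits(variant, "variant_spec"))
  if (kind == "sweep") {
    if (is.null(axis_x) || is.null(axis_y))
      stop("a sweep scenario needs axis_x and axis_y", call. = FALSE)
    stopifnot(inherits(axis_x, "parameter_axis"),
              inherits(axis_y, "parameter_axis"))
    if (!readout %in% ga_species())
      stop("unknown readout species: ", readout, call. = FALSE)
  } else {
    if (!is.numeric(t_end) || t_end <= 0 || !is.numeric(t_step) ||
        t_step <= 0 || t_step >= t_end)
      stop("need 0 < t_step < t_end", call. = FALSE)
  }
  structure(list(name = name, kind = kind, params = params,
                 variant = variant, t_end = t_end, t_step = t_step,
                 axis_x = axis_x, axis_y = axis_y, readout = readout,
                 seed = as.integer(seed)),
            class = "ga_scenario")
}

#' @export
print.ga_scenario <- function(x, ...) {
  cat("GA scenario '", x$name, "' (", x$kind, "), variant ",
      x$variant$variant, " -> ", x$variant$target, "\n", sep = "")
  invisible(x)
}

#' Seeded log-normal parameter ensemble
#'
#' Multiplies every rate constant of `base` by an independent log-normal
#' factor with median 1 and the requested coefficient of variation
#' (`sdlog = sqrt(log(1 + cv^2))`), holding Hill coefficients and the
#' repression exponent fixed.  Multiplicative log-normal noise is the
#' natural perturbation for positive-scale rate constants.  Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param base A [ga_parameters()] set.
#' @param cv Coefficient of variation of the multiplicative factor, >= 0.
#' @param n Number of ensemble members, >= 1.
#' @param seed Integer seed.
#' @return Object of class `"ga_ensemble"`: list with `base`, `members`
#'   (list of `ga_parameters`), `cv`, `seed`.
#' @export
#' @examples
#' ens <- perturb_parameters(default_parameters(), cv = 0.2, n = 3, seed = 7)
#' length(ens$members)
perturb_parameters <- function(base, cv, n, seed) {
  base <- ga_parameters(base)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("cv must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  vary <- setdiff(ga_parameter_names(), .HILL_PARAMS)
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  members <- lapply(seq_len(n), function(i) {
    p <- unclass(base)
    if (cv > 0)
      p[vary] <- p[vary] * exp(stats::rnorm(length(vary), 0, sdlog))
    ga_parameters(p)
  })
  structure(list(base = base, members = members, cv = cv,
                 seed = as.integer(seed)),
            class = "ga_ensemble")
}

#' @export
print.ga_ensemble <- function(x, ...) {
  cat("GA parameter ensemble: n =", length(x$members),
      ", cv =", x$cv, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Ensemble robustness of the qualitative model predictions
#'
#' For each member of a log-normal parameter ensemble, checks the two
#' qualitative predictions at that member's constants: (i) steady-state
#' GA4 of the GAHACR variant is non-increasing along a repression-strength
#' axis and non-decreasing along a degradation-rate axis (checked on a
#' log-spaced grid spanning two decades either side of the member's
#' values), and (ii) the variant ordering wildtype >= GAHACR >= no-degron
#' holds at the member's own constants.  Reports the per-member outcomes
#' and the satisfied fractions; members whose steady states do not all
#' converge are counted as failures, never skipped silently.
#'
#' @param ensemble A [perturb_parameters()] ensemble.
#' @param grid_n Points per sweep axis for the monotonicity check.
#' @param mono_slack Numerical slack on the monotonicity comparisons,
#'   absolute, matched to the steady-state residual tolerance.
#' @param ... Passed to [find_steady_state()] / [sweep_2d()].
#' @return List with `monotone`, `ordered` (logical vectors over members),
#'   `fraction_monotone`, `fraction_ordered`, `fraction_both`.
#' @export
ensemble_robustness <- function(ensemble, grid_n = 8, mono_slack = 1e-7,
                                ...) {
  stopifnot(inherits(ensemble, "ga_ensemble"))
  n <- length(ensemble$members)
  monotone <- logical(n)
  ordered <- logical(n)
  for (i in seq_len(n)) {
    p <- ensemble$members[[i]]
    ax <- parameter_axis("hacr_repstr", log_axis(p[["hacr_repstr"]], grid_n))
    ay <- parameter_axis("hacr_ga_decay",
                         log_axis(p[["hacr_ga_decay"]], grid_n))
    sw <- sweep_2d(p, "gahacr", ax, ay, ...)
    monotone[i] <- all(sw$converged) &&
      all(apply(sw$values, 1, function(r) all(diff(r) <= mono_slack))) &&
      all(apply(sw$values, 2, function(cl) all(diff(cl) >= -mono_slack)))
    ga4 <- vapply(c("wildtype", "gahacr", "no_degron_cr"), function(v) {
      ss <- find_steady_state(ga_model(p, v), ...)
      if (ss$converged) ss$state[["GA4"]] else NA_real_
    }, numeric(1))
    ordered[i] <- !anyNA(ga4) &&
      ga4[["wildtype"]] >= ga4[["gahacr"]] - mono_slack &&
      ga4[["gahacr"]] >= ga4[["no_degron_cr"]] - mono_slack
  }
  list(monotone = monotone, ordered = ordered,
       fraction_monotone = mean(monotone),
       fraction_ordered = mean(ordered),
       fraction_both = mean(monotone & ordered))
}
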