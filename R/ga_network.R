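#' @title GA signaling network with a synthetic CAS9 repressor
#' @name ga_network
#' @description
#' Species roster, kinetic parameters, regulatory-variant rules and the ODE
#' right-hand side of the gibberellin (GA) signaling network.  The baseline
#' network couples the late GA biosynthesis chain
#' (GA12 -> GA15 -> GA24 -> GA9 -> GA4, catalyzed by GA20-oxidase and
#' GA3-oxidase), GA4 perception by the GID1 receptor, degradation of the
#' DELLA repressor through the GA4.GID1 complex, and DELLA's transcriptional
#' feedback: it activates GA20ox, GA3ox and GID1 and represses its own
#' transcription.  The extension adds a GA-regulated Hormone Activated
#' CAS9-based Repressor (GAHACR): a dCas9-degron-repression-domain fusion
#' transcribed constitutively, translated and degraded like DELLA (including
#' GA4.GID1-complex-mediated degradation through its DELLA-derived degron),
#' whose protein abundance enters the denominator of the Hill function
#' driving its target gene's transcription.
NULL

# -- species roster -----------------------------------------------------------

.GA_SPECIES <- c(
  "GA12", "GA15", "GA24", "GA9", "GA4",
  "GA20ox_mRNA", "GA20ox",
  "GA3ox_mRNA", "GA3ox",
  "GID1_mRNA", "GID1",
  "DELLA_mRNA", "DELLA",
  "GA4_GID1", "GA4_GID1_DELLA",
  "HACR_mRNA", "HACR"
)

#' Species roster of the GA network model
#'
#' Ordered identifiers of all state variables: the late biosynthetic
#' intermediates culminating in bioactive GA4, mRNA/protein pairs for
#' GA20ox, GA3ox, GID1 and DELLA, the GA4.GID1 and GA4.GID1.DELLA
#' complexes, and the GAHACR mRNA/protein pair.
#'
#' @return Character vector of species identifiers (length 17).
#' @export
#' @examples
#' ga_species()
ga_species <- function() .GA_SPECIES

# parameters whose value is a Hill coefficient / exponent: held fixed by the
# ensemble perturbation and required to be >= 1
.HILL_PARAMS <- c("n_ga20ox", "n_ga3ox", "n_gid1", "n_della",
                  "hacr_rep_exponent")

.PARAM_NAMES <- c(
  # biosynthesis
  "ga12_synthesis", "k_ga20ox", "k_ga3ox", "ga_turnover", "ga4_turnover",
  # receptor binding and complex-mediated DELLA degradation
  "k_bind", "k_unbind", "complex_turnover",
  # GA20ox transcription unit (activated by DELLA)
  "ga20ox_tx", "ga20ox_mrna_decay", "ga20ox_tl", "ga20ox_decay",
  "K_ga20ox", "n_ga20ox",
  # GA3ox transcription unit (activated by DELLA)
  "ga3ox_tx", "ga3ox_mrna_decay", "ga3ox_tl", "ga3ox_decay",
  "K_ga3ox", "n_ga3ox",
  # GID1 transcription unit (activated by DELLA)
  "gid1_tx", "gid1_mrna_decay", "gid1_tl", "gid1_decay",
  "K_gid1", "n_gid1",
  # DELLA transcription unit (self-repressing) and GA-induced degradation
  "della_tx", "della_mrna_decay", "della_tl", "della_decay",
  "della_ga_decay", "K_della", "n_della",
  # GAHACR block
  "hacr_tx", "hacr_tl", "hacr_mrna_decay", "hacr_protein_decay",
  "hacr_ga_decay", "hacr_repstr", "hacr_rep_exponent"
)

#' Names of all model parameters
#'
#' @return Character vector of the parameter names a [ga_parameters()] set
#'   must contain, in canonical order.
#' @export
ga_parameter_names <- function() .PARAM_NAMES

#' Construct and validate a model parameter set
#'
#' Builds a complete, validated parameter set from a named numeric vector or
#' list.  All rate constants must be finite and non-negative; Hill
#' coefficients (and the repression exponent) must be >= 1.  Unknown names
#' are rejected.
#'
#' @param values Named numeric vector or list covering every name in
#'   [ga_parameter_names()].
#' @return Named numeric vector of class `"ga_parameters"`.
#' @seealso [default_parameters()] for the documented baseline values.
#' @export
ga_parameters <- function(values) {
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("parameter values must be named", call. = FALSE)
  unknown <- setdiff(names(values), .PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.PARAM_NAMES, names(values))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- as.numeric(values[.PARAM_NAMES])
  names(p) <- .PARAM_NAMES
  if (any(!is.finite(p)))
    stop("non-finite parameter(s): ",
         paste(.PARAM_NAMES[!is.finite(p)], collapse = ", "), call. = FALSE)
  if (any(p < 0))
    stop("negative parameter(s): ",
         paste(.PARAM_NAMES[p < 0], collapse = ", "), call. = FALSE)
  hill <- p[.HILL_PARAMS]
  if (any(hill < 1))
    stop("Hill coefficients must be >= 1: ",
         paste(.HILL_PARAMS[hill < 1], collapse = ", "), call. = FALSE)
  K <- p[c("K_ga20ox", "K_ga3ox", "K_gid1", "K_della")]
  if (any(K <= 0))
    stop("Hill thresholds must be > 0: ",
         paste(names(K)[K <= 0], collapse = ", "), call. = FALSE)
  structure(p, class = "ga_parameters")
}

#' @export
print.ga_parameters <- function(x, ...) {
  cat("GA network parameter set (", length(x), " constants)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

# -- variants -----------------------------------------------------------------

.VARIANTS <- c("wildtype", "no_degron_cr", "gahacr")
.TARGETS  <- c("GA20ox", "GA3ox", "GID1", "none")

#' Specify a regulatory variant
#'
#' The three variants compared by the model: `wildtype` (no repressor is
#' expressed), `no_degron_cr` (the repressor lacks the GA degron, so it is
#' not degraded in a GA-dependent manner — an open-loop control), and
#' `gahacr` (the full GA-regulated repressor).  `target` names the
#' transcription unit whose promoter the repressor occupies; `GA20ox` is the
#' default.  Targeting `GA3ox` or `GID1` reuses the same repressed-Hill
#' insertion on those genes' transcription terms and is provided as an
#' experimental option.
#'
#' @param variant One of `"wildtype"`, `"no_degron_cr"`, `"gahacr"`.
#' @param target One of `"GA20ox"`, `"GA3ox"`, `"GID1"`, `"none"`.  Forced
#'   to `"none"` for the wildtype variant.
#' @return A list of class `"variant_spec"` with elements `variant`, `target`.
#' @export
#' @examples
#' variant_spec("gahacr")
#' variant_spec("wildtype")
variant_spec <- function(variant = c("gahacr", "wildtype", "no_degron_cr"),
                         target = c("GA20ox", "GA3ox", "GID1", "none")) {
  variant <- match.arg(variant, .VARIANTS)
  target <- match.arg(target, .TARGETS)
  if (variant == "wildtype") target <- "none"
  if (variant != "wildtype" && target == "none")
    stop("a repressor variant needs a target transcription unit",
         call. = FALSE)
  structure(list(variant = variant, target = target),
            class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("variant:", x$variant, "| target:", x$target, "\n")
  invisible(x)
}

#' Apply a regulatory variant to a parameter set
#'
#' Encodes the variant definitions: the wildtype model sets repressor
#' expression to zero (`hacr_tx = 0`; initial repressor species are also
#' zeroed at simulation setup), the no-degron repressor sets the
#' GA-dependent degradation constant to zero (`hacr_ga_decay = 0`), and the
#' GAHACR variant leaves the set untouched.
#'
#' @param params A [ga_parameters()] set.
#' @param variant A [variant_spec()] or a variant name.
#' @return The adjusted `ga_parameters` set.
#' @export
#' @examples
#' p <- default_parameters()
#' apply_variant(p, "wildtype")[["hacr_tx"]]
#' apply_variant(p, "no_degron_cr")[["hacr_ga_decay"]]
apply_variant <- function(params, variant) {
  if (inherits(variant, "variant_spec")) variant <- variant$variant
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% .VARIANTS)
    stop("unknown variant: ", paste(variant, collapse = ", "),
         call. = FALSE)
  params <- ga_parameters(params)
  switch(variant,
         wildtype = { params[["hacr_tx"]] <- 0 },
         no_degron_cr = { params[["hacr_ga_decay"]] <- 0 },
         gahacr = NULL)
  params
}

# -- regulatory kinetics ------------------------------------------------------

#' Hill activation function
#'
#' Fractional promoter activity `a^n / (K^n + a^n)` of a transcription unit
#' activated by `activator` (in the model, DELLA activating GA20ox, GA3ox
#' and GID1).
#'
#' @param activator Activator concentration(s), >= 0.
#' @param K Half-saturation threshold, > 0.
#' @param n Hill coefficient, >= 1.
#' @return Dimensionless fraction in `[0, 1)`, strictly increasing in
#'   `activator`.
#' @export
#' @examples
#' hill_activation(0.5, K = 0.5, n = 2)   # half saturation -> 0.5
hill_activation <- function(activator, K, n) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single number >= 1", call. = FALSE)
  if (any(activator < 0)) stop("activator must be >= 0", call. = FALSE)
  a <- activator^n
  a / (K^n + a)
}

#' Hill activation opposed by a repressor in the denominator
#'
#' The repressed transcription term used for the GAHACR's target gene:
#' the repressor concentration, scaled by the repression-strength constant
#' `repstr`, is added to the denominator of the activating Hill function,
#' \deqn{\frac{a^n}{K^n + a^n + (\rho\,R)^h},}
#' with exponent `h = 1` by default.  With `repstr = 0` or no repressor the
#' term reduces exactly to [hill_activation()]; for `repstr > 0` it is
#' strictly decreasing in the repressor concentration and tends to zero as
#' the repressor accumulates.
#'
#' @inheritParams hill_activation
#' @param repressor Repressor (GAHACR protein) concentration, >= 0.
#' @param repstr Dimensionless repression strength, >= 0.
#' @param exponent Exponent `h` on the scaled repressor term; default 1.
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
#' @examples
#' repressed_activation(0.5, repressor = 0, repstr = 5, K = 0.5, n = 2)
#' repressed_activation(0.5, repressor = 1, repstr = 5, K = 0.5, n = 2)
repressed_activation <- function(activator, repressor, repstr, K, n,
                                 exponent = 1) {
  if (!is.numeric(repstr) || length(repstr) != 1L || !is.finite(repstr) ||
      repstr < 0)
    stop("repstr must be a single non-negative number", call. = FALSE)
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent < 1)
    stop("exponent must be >= 1", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single number >= 1", call. = FALSE)
  if (any(activator < 0) || any(repressor < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  a <- activator^n
  a / (K^n + a + (repstr * repressor)^exponent)
}

# -- model definition and RHS -------------------------------------------------

#' Assemble a model definition
#'
#' Bundles a parameter set and a regulatory variant into the object consumed
#' by [integrate_model()], [find_steady_state()] and the sweep functions.
#' The variant's parameter adjustments ([apply_variant()]) are applied here,
#' once.
#'
#' @param params A [ga_parameters()] set (pre-variant).
#' @param variant A [variant_spec()], or a variant name (default target
#'   `GA20ox`).
#' @return A list of class `"ga_model"` with elements `species`, `params`
#'   (variant-adjusted), `variant`.
#' @export
#' @examples
#' m <- ga_model(default_parameters(), "gahacr")
#' ga_rhs(initial_state(m), model = m)
ga_model <- function(params = default_parameters(), variant = "wildtype") {
  if (!inherits(variant, "variant_spec")) {
    variant <- if (identical(variant, "wildtype"))
      variant_spec("wildtype") else variant_spec(variant)
  }
  params <- ga_parameters(params)
  structure(list(species = .GA_SPECIES,
                 params = apply_variant(params, variant),
                 variant = variant),
            class = "ga_model")
}

#' @export
print.ga_model <- function(x, ...) {
  cat("GA network model —", length(x$species), "species,",
      length(x$params), "parameters\n")
  print(x$variant)
  invisible(x)
}

#' Default initial state
#'
#' The rest state used throughout: every concentration zero, so each run
#' traces the de-novo rise of the pathway to its homeostatic point.  For the
#' wildtype variant the repressor species are (trivially) zero; for the
#' repressor variants they start at zero as well, i.e. the transgene switches
#' on at t = 0.
#'
#' @param model A [ga_model()] (only used for the species roster).
#' @return Named numeric vector over the model's species, all zeros.
#' @export
initial_state <- function(model = NULL) {
  species <- if (!is.null(model$species)) model$species else .GA_SPECIES
  stats::setNames(numeric(length(species)), species)
}

# shared sub-RHS of a "DELLA-like" regulatory protein: mRNA produced at
# `production` (already including any promoter regulation), first-order mRNA
# decay, translation, basal protein decay, and GA4.GID1-complex-mediated
# protein degradation.  Both the DELLA and the GAHACR equations go through
# this function, which is what makes them structurally identical.
regulatory_unit_rhs <- function(mrna, protein, ga4gid1, production,
                                tl, mrna_decay, protein_decay, ga_decay) {
  c(dmrna = production - mrna_decay * mrna,
    dprotein = tl * mrna - protein_decay * protein -
      ga_decay * ga4gid1 * protein)
}

#' Right-hand side of the GA network ODEs
#'
#' Time-derivative of every species at a given state.  The biosynthetic
#' conversions are mass-action in enzyme and substrate; GA4 binds GID1
#' reversibly; the GA4.GID1 complex captures DELLA irreversibly into a
#' ternary complex whose turnover releases GA4.GID1 (net: GA-induced DELLA
#' degradation, catalytic in GA4.GID1).  DELLA activates GA20ox, GA3ox and
#' GID1 transcription through Hill terms and represses its own transcription.
#' The GAHACR is transcribed constitutively, translated and degraded with
#' the same functional forms as DELLA, and — for non-wildtype variants —
#' enters the denominator of its target gene's transcription term via
#' [repressed_activation()].
#'
#' @param state Named non-negative numeric vector over [ga_species()].
#' @param t Time (the system is autonomous; present for solver interfaces).
#' @param model A [ga_model()].
#' @return Named numeric vector of derivatives, same order as the state.
#' @export
ga_rhs <- function(state, t = 0, model) {
  if (length(state) != length(.GA_SPECIES))
    stop("state must have ", length(.GA_SPECIES), " entries", call. = FALSE)
  bad <- !is.finite(state)
  if (any(bad))
    stop("non-finite state entries: ",
         paste(.GA_SPECIES[bad], collapse = ", "), call. = FALSE)
  p <- model$params
  s <- unname(state)

  ga12 <- s[1L]; ga15 <- s[2L]; ga24 <- s[3L]; ga9 <- s[4L]; ga4 <- s[5L]
  m20 <- s[6L];  p20 <- s[7L]
  m3  <- s[8L];  p3  <- s[9L]
  mg  <- s[10L]; gid1 <- s[11L]
  md  <- s[12L]; della <- s[13L]
  cplx <- s[14L]; tern <- s[15L]
  mh  <- s[16L]; hacr <- s[17L]

  # biosynthetic fluxes (GA20ox catalyzes three oxidations, GA3ox the last)
  v1 <- p[["k_ga20ox"]] * p20 * ga12
  v2 <- p[["k_ga20ox"]] * p20 * ga15
  v3 <- p[["k_ga20ox"]] * p20 * ga24
  v4 <- p[["k_ga3ox"]]  * p3  * ga9

  bind <- p[["k_bind"]] * ga4 * gid1 - p[["k_unbind"]] * cplx
  capture <- p[["della_ga_decay"]] * cplx * della
  release <- p[["complex_turnover"]] * tern

  # promoter activities; the repressor enters only its target's term
  tgt <- model$variant$target
  act20 <- if (tgt == "GA20ox")
    repressed_activation(della, hacr, p[["hacr_repstr"]],
                         p[["K_ga20ox"]], p[["n_ga20ox"]],
                         p[["hacr_rep_exponent"]])
  else hill_activation(della, p[["K_ga20ox"]], p[["n_ga20ox"]])
  act3 <- if (tgt == "GA3ox")
    repressed_activation(della, hacr, p[["hacr_repstr"]],
                         p[["K_ga3ox"]], p[["n_ga3ox"]],
                         p[["hacr_rep_exponent"]])
  else hill_activation(della, p[["K_ga3ox"]], p[["n_ga3ox"]])
  actg <- if (tgt == "GID1")
    repressed_activation(della, hacr, p[["hacr_repstr"]],
                         p[["K_gid1"]], p[["n_gid1"]],
                         p[["hacr_rep_exponent"]])
  else hill_activation(della, p[["K_gid1"]], p[["n_gid1"]])
  # DELLA self-repression: repressive Hill in its own protein
  repd <- p[["K_della"]]^p[["n_della"]] /
    (p[["K_della"]]^p[["n_della"]] + della^p[["n_della"]])

  dd <- regulatory_unit_rhs(md, della, cplx,
                            production = p[["della_tx"]] * repd,
                            tl = p[["della_tl"]],
                            mrna_decay = p[["della_mrna_decay"]],
                            protein_decay = p[["della_decay"]],
                            ga_decay = p[["della_ga_decay"]])
  dh <- regulatory_unit_rhs(mh, hacr, cplx,
                            production = p[["hacr_tx"]],
                            tl = p[["hacr_tl"]],
                            mrna_decay = p[["hacr_mrna_decay"]],
                            protein_decay = p[["hacr_protein_decay"]],
                            ga_decay = p[["hacr_ga_decay"]])

  d <- c(
    p[["ga12_synthesis"]] - v1 - p[["ga_turnover"]] * ga12,
    v1 - v2 - p[["ga_turnover"]] * ga15,
    v2 - v3 - p[["ga_turnover"]] * ga24,
    v3 - v4 - p[["ga_turnover"]] * ga9,
    v4 - bind - p[["ga4_turnover"]] * ga4,
    p[["ga20ox_tx"]] * act20 - p[["ga20ox_mrna_decay"]] * m20,
    p[["ga20ox_tl"]] * m20 - p[["ga20ox_decay"]] * p20,
    p[["ga3ox_tx"]] * act3 - p[["ga3ox_mrna_decay"]] * m3,
    p[["ga3ox_tl"]] * m3 - p[["ga3ox_decay"]] * p3,
    p[["gid1_tx"]] * actg - p[["gid1_mrna_decay"]] * mg,
    p[["gid1_tl"]] * mg - p[["gid1_decay"]] * gid1 - bind,
    dd[[1L]],
    dd[[2L]],
    bind - capture + release,
    capture - release,
    dh[[1L]],
    dh[[2L]]
  )
  if (any(!is.finite(d)))
    stop("non-finite derivative for: ",
         paste(.GA_SPECIES[!is.finite(d)], collapse = ", "), call. = FALSE)
  names(d) <- .GA_SPECIES
  d
}
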