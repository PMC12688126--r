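# Independent transcription of the network equations, written flux-by-flux
# over a named list, deliberately not sharing code with gahacr::ga_rhs().
# `hacr` terms included only when the caller passes hacr constants; with
# the hacr block absent this is the baseline (pre-repressor) model.

oracle_rhs <- function(state, p, variant = "wildtype", target = "none") {
  s <- as.list(state)
  hillA <- function(a, K, n) a^n / (K^n + a^n)
  # promoter activity of a DELLA-activated gene, optionally repressed
  promoter <- function(K, n, repressed) {
    if (repressed && variant != "wildtype")
      s$DELLA^n / (K^n + s$DELLA^n +
                     (p[["hacr_repstr"]] * s$HACR)^p[["hacr_rep_exponent"]])
    else hillA(s$DELLA, K, n)
  }
  flux <- list(
    ga12_in   = p[["ga12_synthesis"]],
    ox1       = p[["k_ga20ox"]] * s$GA20ox * s$GA12,
    ox2       = p[["k_ga20ox"]] * s$GA20ox * s$GA15,
    ox3       = p[["k_ga20ox"]] * s$GA20ox * s$GA24,
    ox4       = p[["k_ga3ox"]] * s$GA3ox * s$GA9,
    assoc     = p[["k_bind"]] * s$GA4 * s$GID1,
    dissoc    = p[["k_unbind"]] * s$GA4_GID1,
    capture   = p[["della_ga_decay"]] * s$GA4_GID1 * s$DELLA,
    release   = p[["complex_turnover"]] * s$GA4_GID1_DELLA
  )
  d <- list()
  d$GA12 <- flux$ga12_in - flux$ox1 - p[["ga_turnover"]] * s$GA12
  d$GA15 <- flux$ox1 - flux$ox2 - p[["ga_turnover"]] * s$GA15
  d$GA24 <- flux$ox2 - flux$ox3 - p[["ga_turnover"]] * s$GA24
  d$GA9  <- flux$ox3 - flux$ox4 - p[["ga_turnover"]] * s$GA9
  d$GA4  <- flux$ox4 - flux$assoc + flux$dissoc -
    p[["ga4_turnover"]] * s$GA4
  d$GA20ox_mRNA <- p[["ga20ox_tx"]] *
    promoter(p[["K_ga20ox"]], p[["n_ga20ox"]], target == "GA20ox") -
    p[["ga20ox_mrna_decay"]] * s$GA20ox_mRNA
  d$GA20ox <- p[["ga20ox_tl"]] * s$GA20ox_mRNA -
    p[["ga20ox_decay"]] * s$GA20ox
  d$GA3ox_mRNA <- p[["ga3ox_tx"]] *
    promoter(p[["K_ga3ox"]], p[["n_ga3ox"]], target == "GA3ox") -
    p[["ga3ox_mrna_decay"]] * s$GA3ox_mRNA
  d$GA3ox <- p[["ga3ox_tl"]] * s$GA3ox_mRNA -
    p[["ga3ox_decay"]] * s$GA3ox
  d$GID1_mRNA <- p[["gid1_tx"]] *
    promoter(p[["K_gid1"]], p[["n_gid1"]], target == "GID1") -
    p[["gid1_mrna_decay"]] * s$GID1_mRNA
  d$GID1 <- p[["gid1_tl"]] * s$GID1_mRNA - p[["gid1_decay"]] * s$GID1 -
    flux$assoc + flux$dissoc
  d$DELLA_mRNA <- p[["della_tx"]] *
    (1 - hillA(s$DELLA, p[["K_della"]], p[["n_della"]])) -
    p[["della_mrna_decay"]] * s$DELLA_mRNA
  d$DELLA <- p[["della_tl"]] * s$DELLA_mRNA -
    p[["della_decay"]] * s$DELLA - flux$capture
  d$GA4_GID1 <- flux$assoc - flux$dissoc - flux$capture + flux$release
  d$GA4_GID1_DELLA <- flux$capture - flux$release
  hacr_tx <- if (variant == "wildtype") 0 else p[["hacr_tx"]]
  hacr_ga <- if (variant == "no_degron_cr") 0 else p[["hacr_ga_decay"]]
  d$HACR_mRNA <- hacr_tx - p[["hacr_mrna_decay"]] * s$HACR_mRNA
  d$HACR <- p[["hacr_tl"]] * s$HACR_mRNA -
    p[["hacr_protein_decay"]] * s$HACR - hacr_ga * s$GA4_GID1 * s$HACR
  unlist(d)[ga_species()]
}

# random non-negative state with a fixed seed offset
random_state <- function(seed, scale = 1) {
  set.seed(seed)
  s <- stats::runif(length(ga_species()), 0, scale)
  names(s) <- ga_species()
  s
}

# random parameter set via the package's own ensemble generator
random_params <- function(seed, cv = 0.3) {
  perturb_parameters(default_parameters(), cv = cv, n = 1,
                     seed = seed)$members[[1]]
}
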