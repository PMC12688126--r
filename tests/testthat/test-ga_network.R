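test_that("hill_activation has the canonical saturating form", {
  expect_equal(hill_activation(0, K = 0.5, n = 2), 0)
  expect_equal(hill_activation(0.5, K = 0.5, n = 2), 0.5)
  # activator = 10 K, n = 2: 100 K^2 / (K^2 + 100 K^2)
  expect_equal(hill_activation(5, K = 0.5, n = 2), 100 / 101)
  # strictly increasing, bounded in [0, 1)
  grid <- seq(0, 20, length.out = 200)
  vals <- hill_activation(grid, K = 0.7, n = 3)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
  expect_error(hill_activation(1, K = 0, n = 2), "K must")
  expect_error(hill_activation(1, K = 1, n = 0.5), "n must")
  expect_error(hill_activation(-1, K = 1, n = 2), "activator")
})

test_that("repressed_activation reduces to Hill and decreases in repressor", {
  for (act in c(0.2, 0.5, 3)) {
    h <- hill_activation(act, K = 0.5, n = 2)
    expect_equal(repressed_activation(act, repressor = 7, repstr = 0,
                                      K = 0.5, n = 2), h)
    expect_equal(repressed_activation(act, repressor = 0, repstr = 5,
                                      K = 0.5, n = 2), h)
  }
  # monotone non-increasing in repressor and in repstr on a 20 x 20 grid
  reps <- seq(0, 10, length.out = 20)
  strs <- seq(0, 10, length.out = 20)
  m <- outer(reps, strs, function(r, s)
    mapply(function(ri, si)
      repressed_activation(1, ri, si, K = 0.5, n = 2), r, s))
  expect_true(all(apply(m, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) <= 0))))
  # strictly decreasing and vanishing when repression is active
  expect_lt(repressed_activation(1, 5, 2, K = 0.5, n = 2),
            repressed_activation(1, 1, 2, K = 0.5, n = 2))
  expect_lt(repressed_activation(1, 1e8, 2, K = 0.5, n = 2), 1e-6)
  expect_error(repressed_activation(1, 1, repstr = -1, K = 0.5, n = 2),
               "repstr")
})

test_that("parameter sets validate rates, Hill coefficients and names", {
  p <- default_parameters()
  expect_s3_class(p, "ga_parameters")
  expect_setequal(names(p), ga_parameter_names())
  bad <- unclass(p); bad[["k_bind"]] <- -1
  expect_error(ga_parameters(bad), "negative")
  bad <- unclass(p); bad[["n_della"]] <- 0.5
  expect_error(ga_parameters(bad), "Hill")
  bad <- c(unclass(p), not_a_rate = 1)
  expect_error(ga_parameters(bad), "not_a_rate")
  expect_error(ga_parameters(unclass(p)[-1]), "missing")
})

test_that("variant rules: wildtype silences expression, no-degron removes GA decay", {
  p <- default_parameters()
  wt <- apply_variant(p, "wildtype")
  expect_identical(wt[["hacr_tx"]], 0)
  expect_identical(unclass(wt)[setdiff(names(p), "hacr_tx")],
                   unclass(p)[setdiff(names(p), "hacr_tx")])
  nd <- apply_variant(p, "no_degron_cr")
  expect_identical(nd[["hacr_ga_decay"]], 0)
  expect_identical(unclass(nd)[setdiff(names(p), "hacr_ga_decay")],
                   unclass(p)[setdiff(names(p), "hacr_ga_decay")])
  expect_identical(unclass(apply_variant(p, "gahacr")), unclass(p))
  expect_error(apply_variant(p, "cas9"), "unknown variant")
  expect_identical(variant_spec("wildtype")$target, "none")
  expect_error(variant_spec("gahacr", "none"), "target")
})

test_that("rhs matches an independent transcription on random states", {
  for (seed in 1:10) {
    p <- random_params(seed)
    s <- random_state(seed + 100, scale = 2)
    for (v in c("wildtype", "no_degron_cr", "gahacr")) {
      model <- ga_model(p, v)
      expect_equal(ga_rhs(s, 0, model),
                   oracle_rhs(s, p, variant = v, target = "GA20ox"),
                   tolerance = 1e-12)
    }
  }
})

test_that("rhs reduces to the baseline model when the repressor is absent", {
  p <- default_parameters()
  wt <- ga_model(p, "wildtype")
  for (seed in 1:5) {
    s <- random_state(seed, scale = 2)
    s[c("HACR_mRNA", "HACR")] <- 0
    d <- ga_rhs(s, 0, wt)
    # term-by-term identical to the oracle with the repressor block silent
    expect_equal(d, oracle_rhs(s, p, variant = "wildtype"),
                 tolerance = 1e-14)
    expect_identical(unname(d[c("HACR_mRNA", "HACR")]), c(0, 0))
  }
  # repstr = 0: target transcription equals the unrepressed Hill term
  p0 <- p; p0[["hacr_repstr"]] <- 0
  g <- ga_model(ga_parameters(p0), "gahacr")
  s <- random_state(42, scale = 2)
  d <- ga_rhs(s, 0, g)
  expected <- p[["ga20ox_tx"]] *
    hill_activation(s[["DELLA"]], p[["K_ga20ox"]], p[["n_ga20ox"]]) -
    p[["ga20ox_mrna_decay"]] * s[["GA20ox_mRNA"]]
  expect_equal(unname(d[["GA20ox_mRNA"]]), unname(expected))
})

test_that("no species is consumed at the zero state (forward invariance)", {
  zero <- initial_state()
  for (v in c("wildtype", "no_degron_cr", "gahacr")) {
    d <- ga_rhs(zero, 0, ga_model(default_parameters(), v))
    expect_true(all(d >= 0))
  }
  # also under random parameter draws
  for (seed in 1:5)
    expect_true(all(ga_rhs(zero, 0, ga_model(random_params(seed),
                                             "gahacr")) >= 0))
})

test_that("repressor sub-equations mirror DELLA's with equalized constants", {
  p <- unclass(default_parameters())
  p[c("hacr_tx", "hacr_tl", "hacr_mrna_decay", "hacr_protein_decay",
      "hacr_ga_decay")] <-
    p[c("della_tx", "della_tl", "della_mrna_decay", "della_decay",
        "della_ga_decay")]
  model <- ga_model(ga_parameters(p), "gahacr")
  for (seed in 1:10) {
    s <- random_state(seed, scale = 2)
    # place the repressor at DELLA's concentrations
    s[["HACR_mRNA"]] <- s[["DELLA_mRNA"]]
    s[["HACR"]] <- s[["DELLA"]]
    d <- ga_rhs(s, 0, model)
    # translation/decay/GA-induced-decay structure is identical; the only
    # difference is the promoter input (DELLA self-represses, the
    # repressor cassette is constitutive)
    della_production <- p[["della_tx"]] * p[["K_della"]]^p[["n_della"]] /
      (p[["K_della"]]^p[["n_della"]] + s[["DELLA"]]^p[["n_della"]])
    expect_equal(unname(d[["HACR_mRNA"]] - d[["DELLA_mRNA"]]),
                 unname(p[["hacr_tx"]] - della_production))
    expect_equal(unname(d[["HACR"]]), unname(d[["DELLA"]]))
  }
})

test_that("rhs rejects malformed states and reports the offending species", {
  model <- ga_model(default_parameters(), "gahacr")
  s <- initial_state()
  s[["GA4"]] <- NaN
  expect_error(ga_rhs(s, 0, model), "GA4")
  expect_error(ga_rhs(numeric(3), 0, model), "17")
})

test_that("rhs is finite on extreme but admissible states", {
  model <- ga_model(default_parameters(), "gahacr")
  for (scale in c(1e-8, 1, 1e4)) {
    s <- random_state(7, scale = scale)
    expect_true(all(is.finite(ga_rhs(s, 0, model))))
  }
})
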