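test_that("a degenerate 1x1 grid reproduces find_steady_state", {
  p <- default_parameters()
  sw <- sweep_2d(p, "gahacr",
                 parameter_axis("hacr_repstr", p[["hacr_repstr"]]),
                 parameter_axis("hacr_ga_decay", p[["hacr_ga_decay"]]))
  ss <- find_steady_state(ga_model(p, "gahacr"))
  expect_identical(dim(sw$values), c(1L, 1L))
  expect_true(sw$converged[1, 1])
  expect_equal(sw$values[1, 1], unname(ss$state[["GA4"]]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sweep axes are validated before any simulation", {
  p <- default_parameters()
  expect_error(parameter_axis("hacr_represion", 1:3), "unknown parameter")
  expect_error(parameter_axis("hacr_repstr", c(2, 1)), "increasing")
  expect_error(sweep_2d(p, "gahacr",
                        parameter_axis("hacr_repstr", 1:3),
                        parameter_axis("hacr_repstr", 1:3)),
               "distinct")
  expect_error(sweep_2d(p, "gahacr",
                        parameter_axis("hacr_repstr", 1:2),
                        parameter_axis("hacr_ga_decay", 1:2),
                        readout = "GA99"), "readout")
})

test_that("steady GA4 falls with repression strength, rises with degradation", {
  p <- default_parameters()
  sw <- sweep_2d(p, "gahacr",
                 parameter_axis("hacr_repstr",
                                exp(seq(log(0.01), log(100), length.out = 8))),
                 parameter_axis("hacr_ga_decay", c(0.5, 5, 50)))
  expect_true(all(sw$converged))
  # each row: non-increasing along the repression-strength axis
  for (j in seq_len(nrow(sw$values)))
    expect_true(all(diff(sw$values[j, ]) <= 1e-8))
  # each column: non-decreasing along the degradation axis
  for (i in seq_len(ncol(sw$values)))
    expect_true(all(diff(sw$values[, i]) >= -1e-8))
})

test_that("repeated sweeps with identical inputs are bit-identical", {
  p <- default_parameters()
  ax <- parameter_axis("hacr_repstr", c(0.1, 1, 10))
  ay <- parameter_axis("hacr_ga_decay", c(0.5, 50))
  sw1 <- sweep_2d(p, "gahacr", ax, ay)
  sw2 <- sweep_2d(p, "gahacr", ax, ay)
  expect_identical(sw1$values, sw2$values)
  expect_identical(sw1$converged, sw2$converged)
})

test_that("the three variants coincide when repression cannot act", {
  # hacr_repstr = 0: repressor is expressed but transcriptionally inert
  p <- unclass(default_parameters()); p[["hacr_repstr"]] <- 0
  cmp <- compare_variants(ga_parameters(p), times = seq(0, 100, by = 1),
                          rel_tol = 1e-10, abs_tol = 1e-12)
  ga4 <- lapply(cmp$variants, function(v) v$trajectory$state[, "GA4"])
  expect_equal(ga4$wildtype, ga4$gahacr, tolerance = 1e-8)
  expect_equal(ga4$wildtype, ga4$no_degron_cr, tolerance = 1e-8)
  # hacr_tx = 0: no repressor is ever made, all variants are wildtype
  p2 <- unclass(default_parameters()); p2[["hacr_tx"]] <- 0
  cmp2 <- compare_variants(ga_parameters(p2), times = seq(0, 50, by = 1),
                           rel_tol = 1e-10, abs_tol = 1e-12)
  ga4b <- lapply(cmp2$variants, function(v) v$trajectory$state[, "GA4"])
  expect_equal(ga4b$wildtype, ga4b$gahacr, tolerance = 1e-8)
  expect_equal(ga4b$wildtype, ga4b$no_degron_cr, tolerance = 1e-8)
})

test_that("active repression orders the variants: WT >= GAHACR >= no-degron", {
  cmp <- compare_variants(default_parameters(), times = seq(0, 50, by = 1))
  ga4 <- vapply(cmp$variants, function(v) v$steady_state$state[["GA4"]],
                numeric(1))
  expect_true(all(vapply(cmp$variants,
                         function(v) v$steady_state$converged, logical(1))))
  expect_gte(ga4[["wildtype"]], ga4[["gahacr"]])
  expect_gte(ga4[["gahacr"]], ga4[["no_degron_cr"]])
  # and strictly so at the default constants
  expect_gt(ga4[["wildtype"]], ga4[["gahacr"]] * (1 + 1e-6))
  expect_gt(ga4[["gahacr"]], ga4[["no_degron_cr"]] * (1 + 1e-6))
})

test_that("relative_reduction is exact arithmetic and bounded on sweeps", {
  p <- default_parameters()
  baseline <- find_steady_state(ga_model(p, "wildtype"))
  sw <- sweep_2d(p, "gahacr",
                 parameter_axis("hacr_repstr", c(0.1, 1, 10)),
                 parameter_axis("hacr_ga_decay", c(0.5, 5)))
  rr <- relative_reduction(sw, baseline)
  b <- baseline$state[["GA4"]]
  expect_equal(rr, (b - sw$values) / b, ignore_attr = TRUE)
  # repression can only lower GA4 below the no-repressor baseline
  expect_true(all(rr >= -1e-6 & rr <= 1))
  fake <- baseline; fake$converged <- FALSE
  expect_error(relative_reduction(sw, fake), "converge")
})

test_that("nonlinearity_score is zero for lines, positive for curves", {
  x <- 1:5
  expect_equal(nonlinearity_score(x, 2 * x + 1), 0)
  expect_equal(nonlinearity_score(x, rep(3, 5)), 0)
  x2 <- seq(0, 1, length.out = 5)
  expect_gt(nonlinearity_score(x2, x2^2), 0)
  expect_error(nonlinearity_score(1:3, 1:3), "at least 4")
  expect_error(nonlinearity_score(c(1, 1, 2, 3), 1:4), "increasing")
})

test_that("expression ramps contrast the closed- and open-loop repressors", {
  tx <- exp(seq(log(0.05), log(5), length.out = 6))
  ga <- expression_ramp(default_parameters(), "gahacr", tx)
  nd <- expression_ramp(default_parameters(), "no_degron_cr", tx)
  expect_true(all(ga$converged) && all(nd$converged))
  # more repressor expression always means less GA4, for both variants
  expect_true(all(diff(ga$readout) <= 1e-8))
  expect_true(all(diff(nd$readout) <= 1e-8))
  # feedback keeps the GAHACR's GA4 above the open-loop repressor's
  expect_true(all(ga$readout >= nd$readout - 1e-8))
})
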