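test_that("GORICA values and weights reproduce the published tables from
           their printed inputs", {
  for (rows in list(printed_degrees_rows(), printed_gaze_rows())) {
    vals <- gorica_value(rows$loglik, rows$penalty)
    expect_equal(vals, rows$gorica, tolerance = 0.002 / max(abs(rows$gorica)))
    w <- gorica_weights(rows$gorica)
    expect_equal(w, rows$weight, tolerance = 0.002 / max(rows$weight))
  }
  expect_equal(gorica_value(0, 0), 0)
})

test_that("weight transforms have the exponential-ratio structure", {
  expect_equal(gorica_weights(c(5, 5)), c(0.5, 0.5))
  w <- gorica_weights(c(0, 2 * log(9)))
  expect_equal(w[1] / w[2], 9, tolerance = 1e-10)
  expect_equal(sum(gorica_weights(c(-3, 1, 7))), 1, tolerance = 1e-12)
})

test_that("penalty weights match the published comparisons", {
  expect_equal(round(penalty_weights(c(6.322, 7.000)), 3), c(0.663, 0.337))
  expect_equal(round(penalty_weights(c(2.547, 4.000)), 3), c(0.810, 0.190))
  expect_equal(round(penalty_weights(c(1.000, 4.000)), 3), c(0.953, 0.047))
  expect_equal(sum(penalty_weights(c(1, 2, 3))), 1, tolerance = 1e-12)
})

test_that("the full pipeline ranks the degrees hypotheses and satisfies
           the table invariants", {
  tab <- load_fixture("degrees")
  sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
  hs <- degrees_hypothesis_set()
  gt <- evaluate_set(tab, sp, hs, B = 400, T = 4000, seed = 12)
  expect_equal(attr(gt, "best"), "H2")
  expect_equal(sum(gt$weight), 1, tolerance = 1e-10)
  expect_equal(sum(gt$penalty_weight), 1, tolerance = 1e-10)
  expect_equal(gt$gorica, -2 * gt$loglik + 2 * gt$penalty, tolerance = 1e-12)
  expect_equal(which.min(gt$gorica), which.max(gt$weight))
  expect_equal(gt$label[nrow(gt)], "Hu")
  expect_equal(gt$penalty[nrow(gt)], 4)   # failsafe penalty exactly K
})

test_that("adding the failsafe preserves the relative weights of the
           theory-based hypotheses", {
  tab <- load_fixture("degrees")
  sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
  hyps <- degrees_hypothesis_set()$hypotheses
  with_u <- evaluate_set(tab, sp, hypothesis_set(hyps), B = 300, T = 3000,
                         seed = 4)
  without_u <- evaluate_set(tab, sp,
                            hypothesis_set(hyps,
                                           include_unconstrained = FALSE),
                            B = 300, T = 3000, seed = 4)
  r1 <- with_u$weight[1:3] / with_u$weight[1]
  r2 <- without_u$weight[1:3] / without_u$weight[1]
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("equality-only sets reproduce the AIC ordering", {
  tab <- load_fixture("degrees")
  sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
  nm <- sp$names
  hyps <- list(parse_hypothesis("eta1 = eta2", nm, "E1"),
               parse_hypothesis("eta1 = eta2; eta3 = eta4", nm, "E2"),
               parse_hypothesis("eta1 = eta2 = eta3 = eta4", nm, "E3"))
  gt <- evaluate_set(tab, sp, hypothesis_set(hyps), B = 500, T = 1000,
                     seed = 3)
  # independent AIC: -2 * restricted loglik + 2 * (K - rank(S))
  est <- ensure_positive_definite(
    bootstrap_estimate(tab, sp, B = 500, seed = 3))
  aic <- vapply(c(hyps, list(unconstrained_hypothesis(nm))), function(h) {
    ll <- if (nrow(h$S)) restricted_mle(est, h)$loglik else
      unconstrained_loglik(est)
    -2 * ll + 2 * (4 - qr(h$S)$rank)
  }, numeric(1))
  expect_equal(order(gt$gorica), order(aic))
  expect_equal(gt$penalty, c(3, 2, 1, 4))
})

test_that("a single-failsafe set gets weight one and reports are written", {
  tab <- load_fixture("degrees")
  sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
  hu_only <- hypothesis_set(list(unconstrained_hypothesis(sp$names)),
                            include_unconstrained = FALSE)
  gt <- evaluate_set(tab, sp, hu_only, B = 100, T = 500, seed = 2)
  expect_equal(nrow(gt), 1)
  expect_equal(gt$weight, 1)
  for (fmt in c("csv", "json", "text")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_gorica_table(gt, f, fmt)
    expect_true(file.size(f) > 0)
  }
  f <- tempfile(fileext = ".csv")
  write_gorica_table(gt, f, "csv")
  expect_equal(utils::read.csv(f)$weight, 1)
})

test_that("stage errors are labeled with their stage", {
  tab <- contingency_table(c(5, 0, 15, 7, 3, 8, 0, 6), dims = c(2, 4))
  sp <- builtin_spec("local_odds_ratio", c(2, 4))
  h <- parse_hypothesis("or11 > 1", sp$names, "H")
  expect_error(
    evaluate_set(tab, sp, hypothesis_set(list(h)), B = 50, T = 100, seed = 1),
    "stage")
})
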