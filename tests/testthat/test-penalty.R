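nm2 <- c("t1", "t2")
nm4 <- paste0("e", 1:4)

test_that("closed-form penalties cover the degenerate level distributions", {
  hu <- unconstrained_hypothesis(nm4)
  expect_equal(penalty_closed_form(hu)$pt, 4)
  heq <- parse_hypothesis("e1 = e2 = e3 = e4", nm4, "H2")
  expect_equal(penalty_closed_form(heq)$pt, 1)
  nm12 <- paste0("m", 1:12)
  h4 <- parse_hypothesis("m1 = m2; m3 = m4; m5 = m6; m7 = m8", nm12, "H")
  expect_equal(penalty_closed_form(h4)$pt, 8)
  # redundant equality rows are counted by rank, not row number
  hred <- parse_hypothesis("e1 = e2; 2*e1 - 2*e2 = 0", nm4, "H")
  expect_equal(penalty_closed_form(hred)$pt, 3)
  hin <- parse_hypothesis("e1 > e2", nm4, "H")
  expect_null(penalty_closed_form(hin))
  # the MC path short-circuits to the same exact values
  expect_equal(penalty_mc(heq, diag(4), T = 10)$pt, 1)
})

test_that("textbook penalties under an identity covariance are recovered", {
  h1 <- parse_hypothesis("t1 > 0; t2 > 0", nm2, "H1")
  h2 <- parse_hypothesis("t1 > t2", nm2, "H2")
  p1 <- penalty_mc(h1, diag(2), T = 40000, seed = 31)
  p2 <- penalty_mc(h2, diag(2), T = 40000, seed = 32)
  expect_equal(p1$pt, 1, tolerance = 3 * p1$mc_se / 1)
  expect_equal(unname(p1$level_probs[2:3]), c(0.50, 0.25), tolerance = 0.02)
  expect_equal(p2$pt, 1.5, tolerance = 3 * p2$mc_se / 1.5)
  expect_equal(unname(p2$level_probs[2:3]), c(0.50, 0.50), tolerance = 0.02)
  expect_equal(sum(p1$level_probs), 1, tolerance = 1e-12)
})

test_that("the orthant level probability matches the closed form under
           correlation", {
  h <- parse_hypothesis("t1 > 0; t2 > 0", nm2, "H")
  for (rho in c(-0.5, 0, 0.6)) {
    sigma <- matrix(c(1, rho, rho, 1), 2)
    p <- penalty_mc(h, sigma, T = 40000, seed = 40 + round(10 * rho))
    expected <- orthant_prob(rho)
    se <- sqrt(expected * (1 - expected) / p$T)
    expect_equal(unname(p$level_probs[3]), expected, tolerance = 3 * se / expected)
  }
})

test_that("penalties are invariant to covariance scaling after relocation", {
  sigma <- printed_degrees_sigma()
  hyps <- list(parse_hypothesis("e1 > {e2, e3, e4}", nm4, "A"),
               parse_hypothesis("e1 - e2 > 0.8", nm4, "B"),
               parse_hypothesis("e1 = e2; e3 > e4", nm4, "C"))
  for (h in hyps) {
    p1 <- penalty_mc(h, sigma, T = 20000, seed = 51)
    p2 <- penalty_mc(h, 1e5 * sigma, T = 20000, seed = 52)
    expect_equal(p1$pt, p2$pt,
                 tolerance = 3 * (p1$mc_se + p2$mc_se) / p1$pt)
  }
})

test_that("inequality-only penalties respect the sandwich bounds", {
  set.seed(9)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4)
    sigma <- crossprod(A) + 0.5 * diag(4)
    h <- parse_hypothesis("e1 > e2; e2 > e3; e3 > e4", nm4, "H")
    p <- penalty_mc(h, sigma, T = 4000, seed = i)
    expect_gte(p$pt, 4 - 3)
    expect_lte(p$pt, 4)
    expect_equal(sum(p$level_probs), 1, tolerance = 1e-12)
  }
})

test_that("the bounded-simplex penalty is exact when the covariance ball
           stays inside the simplex", {
  est <- bootstrap_estimate(load_fixture("degrees"),
                            builtin_spec("cells", c(2, 4), drop_last = FALSE),
                            B = 500, seed = 3)
  hp <- pi_hypothesis(c(2, 4))
  p <- penalty_bounded_pi(hp, est$sigma_hat,
                          bounded_penalty_config(c = 1, T = 500), seed = 6)
  expect_equal(p$pt, 7, tolerance = 0.05 / 7)
  # at a large scale the simplex bounds bite and the penalty collapses
  p2 <- penalty_bounded_pi(hp, est$sigma_hat,
                           bounded_penalty_config(c = 1e5, T = 1000),
                           seed = 6)
  expect_lt(p2$pt, 7 - 3 * p2$mc_se)
})

test_that("the non-linear bounded penalty reproduces the conditional-ratio
           demonstration at unit scale", {
  est <- bootstrap_estimate(load_fixture("degrees"),
                            builtin_spec("cells", c(2, 4), drop_last = FALSE),
                            B = 500, seed = 3)
  spc <- builtin_spec("conditional_row", c(2, 4), row = 2)
  h1 <- parse_hypothesis("eta1 > {eta2, eta3, eta4}", spc$names, "H1")
  hp <- pi_hypothesis(c(2, 4), spc, h1)
  p <- penalty_bounded_pi(hp, est$sigma_hat,
                          bounded_penalty_config(c = 1, T = 400), seed = 6)
  expect_equal(p$pt, 6.322, tolerance = 0.2 / 6.322)
})

test_that("penalty results serialize to JSON", {
  h <- parse_hypothesis("t1 > t2", nm2, "H")
  p <- penalty_mc(h, diag(2), T = 2000, seed = 1)
  txt <- penalty_to_json(p)
  back <- jsonlite::fromJSON(txt)
  expect_equal(back$pt, p$pt)
  expect_equal(unlist(back$level_probs), p$level_probs)
})
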