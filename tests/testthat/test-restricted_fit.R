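test_that("projection onto a single equality matches the closed form", {
  h <- parse_hypothesis("a = b", c("a", "b"), "H")
  fit <- restricted_mle(list(eta_hat = c(1, 0), sigma_hat = diag(2)), h)
  expect_equal(unname(fit$eta_tilde), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(fit$quad_form, 0.5, tolerance = 1e-10)
})

test_that("unconstrained log-likelihood matches the closed form and the
           published covariance matrices", {
  expect_equal(unconstrained_loglik(matrix(1)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(unconstrained_loglik(printed_degrees_sigma()), 10.267,
               tolerance = 0.05 / 10.267)
  expect_equal(unconstrained_loglik(printed_gaze_sigma()), 68.654,
               tolerance = 0.05 / 68.654)
  expect_error(unconstrained_loglik(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("estimates already satisfying the constraints fit perfectly", {
  # the gaze data satisfy the shifted-eyes interaction ordering exactly
  sp <- spec_from_yaml(system.file("extdata", "eyetracking_spec.yaml",
                                   package = "goricct"))
  est <- bootstrap_estimate(load_fixture("eyetracking"), sp, B = 300,
                            seed = 21)
  est <- ensure_positive_definite(est)
  hs <- read_hypothesis_file(
    system.file("extdata", "eyetracking_hypotheses.txt", package = "goricct"),
    sp$names)
  fit <- restricted_mle(est, hs$hypotheses[[2]])   # H2
  expect_equal(fit$quad_form, 0, tolerance = 1e-10)
  expect_equal(fit$loglik, unconstrained_loglik(est), tolerance = 1e-8)
  # projection idempotence
  est2 <- est
  est2$eta_hat$values <- unname(fit$eta_tilde)
  fit2 <- restricted_mle(est2, hs$hypotheses[[1]])
  fit3 <- restricted_mle(list(eta_hat = unname(fit2$eta_tilde),
                              sigma_hat = est$sigma_hat),
                         hs$hypotheses[[1]])
  expect_equal(fit3$quad_form, 0, tolerance = 1e-10)
})

test_that("adding constraints never increases the restricted loglik", {
  set.seed(14)
  nm <- c("a", "b", "c")
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3)
    sigma <- crossprod(A) + diag(3) * 0.1
    est <- list(eta_hat = rnorm(3), sigma_hat = sigma)
    h1 <- parse_hypothesis("a > b", nm, "H1")
    h2 <- parse_hypothesis("a > b; b > c", nm, "H2")
    h3 <- parse_hypothesis("a > b; b > c; a > 0.5", nm, "H3")
    lls <- c(unconstrained_loglik(sigma),
             restricted_mle(est, h1)$loglik,
             restricted_mle(est, h2)$loglik,
             restricted_mle(est, h3)$loglik)
    expect_true(all(diff(lls) <= 1e-10))
  }
})

test_that("the projection agrees with an independent grid minimizer on
           K <= 3 systems", {
  set.seed(8)
  nm2 <- c("a", "b")
  nm3 <- c("a", "b", "c")
  cases <- list(
    list(nm = nm2, txt = "a = b", eta = c(1, 0), sigma = diag(2)),
    list(nm = nm2, txt = "a - b > 0.8", eta = c(0, 0.5),
         sigma = matrix(c(1, 0.4, 0.4, 1), 2)),
    list(nm = nm2, txt = "a > 0; b > 0", eta = c(-1, -2), sigma = diag(2)),
    list(nm = nm3, txt = "a > b > c", eta = c(0, 1, 2),
         sigma = diag(c(1, 2, 0.5))),
    list(nm = nm3, txt = "a = b; c > 0.3", eta = c(1, 0, 0),
         sigma = matrix(c(1, 0.3, 0, 0.3, 1, 0.2, 0, 0.2, 1), 3)))
  for (cs in cases) {
    h <- parse_hypothesis(cs$txt, cs$nm, "H")
    fit <- restricted_mle(list(eta_hat = cs$eta, sigma_hat = cs$sigma), h)
    oracle <- grid_projection_oracle(cs$eta, cs$sigma, h$S, h$s, h$R, h$r)
    expect_equal(unname(fit$eta_tilde), unname(oracle), tolerance = 1e-4)
  }
})

test_that("constraint feasibility is validated", {
  nm <- c("a", "b")
  bad <- parse_hypothesis("a = b; a - b > 0", nm, "H")
  bad$S <- rbind(c(1, -1), c(1, -1))
  bad$s <- c(0, 1)   # inconsistent pair of equalities
  expect_error(restricted_mle(list(eta_hat = c(0, 0), sigma_hat = diag(2)),
                              bad),
               "inconsistent")
  est <- list(eta_hat = c(NA_real_, 1), sigma_hat = diag(2))
  h <- parse_hypothesis("a > b", nm, "H")
  expect_error(restricted_mle(est, h), "inestimable")
})

test_that("active sets come from residuals at the stated tolerance", {
  h <- parse_hypothesis("a > 0; b > 0", c("a", "b"), "H")
  fit <- restricted_mle(list(eta_hat = c(-1, 2), sigma_hat = diag(2)), h)
  # exactly the a > 0 row is active (rows are in normalized order)
  expect_length(fit$active$inequality, 1)
  expect_equal(h$R[fit$active$inequality, ], c(1, 0))
  expect_equal(unname(fit$eta_tilde), c(0, 2), tolerance = 1e-10)
})
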