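test_that("conditional proportions on the degrees table match the ratios", {
  sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
  expect_length(sp$terms, 4)
  ev <- eta_value(sp, mle_probabilities(load_fixture("degrees")))
  expect_equal(unname(ev$values[1]), 661 / 1594, tolerance = 1e-12)
  expect_equal(round(ev$values, 3), c(0.415, 0.393, 0.463, 0.500),
               ignore_attr = TRUE)
  expect_true(all(ev$flags == "ok"))
})

test_that("marginal patterns recover published gaze margins", {
  sp <- spec_from_yaml(system.file("extdata", "eyetracking_spec.yaml",
                                   package = "goricct"))
  expect_identical(sp$names[5], "p33_")
  ev <- eta_value(sp, mle_probabilities(load_fixture("eyetracking")))
  expect_equal(round(unname(ev$values[5]), 3), 0.410)   # pi_33+
  expect_equal(round(unname(ev$values[1]), 3), 0.017)   # pi_11+
  expect_equal(ev$flags[3], "zero")                     # pi_22+ empty
  expect_equal(ev$flags[4], "zero")                     # pi_2+2 empty
})

test_that("degenerate eta estimates are flagged, not raised", {
  # empty numerator and denominator cells in a sparse 2x4 table: the first
  # local odds ratio has an empty denominator cell
  tab <- contingency_table(c(5, 0, 15, 7, 3, 8, 0, 6), dims = c(2, 4))
  sp <- builtin_spec("local_odds_ratio", c(2, 4))
  expect_length(sp$terms, 3)
  ev <- eta_value(sp, mle_probabilities(tab))
  expect_equal(ev$flags[1], "inestimable")
  expect_true(is.na(ev$values[1]))
  # a conditional proportion estimated as exactly one
  tab2 <- contingency_table(c(7, 5, 8, 0), dims = c(2, 2))
  ev2 <- eta_value(builtin_spec("conditional_row", c(2, 2), row = 1),
                   mle_probabilities(tab2))
  expect_equal(ev2$flags[2], "one")
  expect_equal(unname(ev2$values[2]), 1)
  # a conditional proportion estimated as exactly zero
  tab3 <- contingency_table(c(7, 0, 3, 2), dims = c(2, 2))
  ev3 <- eta_value(builtin_spec("conditional_row", c(2, 2), row = 1),
                   mle_probabilities(tab3))
  expect_equal(ev3$flags[2], "zero")
})

test_that("builtin families have the catalog sizes and conventions", {
  expect_length(builtin_spec("local_odds_ratio", c(2, 4))$terms, 3)
  expect_length(builtin_spec("marginal_odds_ratio", c(4, 4, 4),
                             axis = 1)$terms, 9)
  expect_length(builtin_spec("conditional_odds_ratio", c(4, 4, 4),
                             fix_axis = 2, fix_level = 1)$terms, 9)
  expect_error(builtin_spec("marginal_odds_ratio", c(2, 4)), ">= 3")
  expect_error(builtin_spec("local_odds_ratio", c(2, 4, 2)), "2-way")
  expect_length(builtin_spec("cells", c(2, 4))$terms, 7)       # last dropped
  expect_length(builtin_spec("cells", c(2, 4), drop_last = FALSE)$terms, 8)
})

test_that("complementary conditional rows satisfy eta = 1 - eta*", {
  p <- mle_probabilities(load_fixture("degrees"))
  male <- eta_value(builtin_spec("conditional_row", c(2, 4), row = 2), p)
  female <- eta_value(builtin_spec("conditional_row", c(2, 4), row = 1), p)
  expect_equal(unname(male$values), 1 - unname(female$values),
               tolerance = 1e-12)
})

test_that("odds ratios are one under exact independence", {
  set.seed(3)
  rm <- c(0.3, 0.7); cm <- c(0.1, 0.2, 0.3, 0.4)
  p2 <- probability_vector(as.vector(t(outer(rm, cm))), c(2, 4))
  lor <- eta_value(builtin_spec("local_odds_ratio", c(2, 4)), p2)
  expect_equal(unname(lor$values), rep(1, 3), tolerance = 1e-10)
  m1 <- c(0.2, 0.3, 0.5); m2 <- c(0.25, 0.25, 0.5); m3 <- c(0.1, 0.4, 0.5)
  vals <- as.vector(aperm(outer(outer(m1, m2), m3), c(1, 2, 3)))
  # row-major flat order over (i, j, v)
  flat <- numeric(27)
  for (i in 1:3) for (j in 1:3) for (v in 1:3) {
    flat[cell_index(c(i, j, v), c(3, 3, 3))] <- m1[i] * m2[j] * m3[v]
  }
  p3 <- probability_vector(flat, c(3, 3, 3))
  mor <- eta_value(builtin_spec("marginal_odds_ratio", c(3, 3, 3), axis = 1),
                   p3)
  cor_ <- eta_value(builtin_spec("conditional_odds_ratio", c(3, 3, 3),
                                 fix_axis = 1, fix_level = 2), p3)
  expect_equal(unname(mor$values), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(cor_$values), rep(1, 4), tolerance = 1e-10)
})

test_that("uniform distributions give equal conditional components", {
  p <- probability_vector(rep(1 / 8, 8), c(2, 4))
  ev <- eta_value(builtin_spec("conditional_row", c(2, 4), row = 2), p)
  expect_equal(unname(ev$values), rep(0.5, 4), tolerance = 1e-12)
})

test_that("specs serialize to YAML and back", {
  sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
  txt <- spec_to_yaml(sp)
  sp2 <- spec_from_yaml(txt, text = TRUE)
  expect_identical(sp2$names, sp$names)
  expect_identical(sp2$terms, sp$terms)
  expect_identical(sp2$dims, sp$dims)
})

test_that("mixing term kinds in one spec warns", {
  expect_warning(
    eta_spec("custom_ratio",
             list(list(type = "sum", a = 1L, b = NULL, c = NULL, d = NULL),
                  list(type = "ratio", a = 1L, b = c(1L, 2L), c = NULL,
                       d = NULL)),
             c("a", "b"), c(2, 2)),
    "mixes term types")
})
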