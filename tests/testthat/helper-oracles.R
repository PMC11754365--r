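# Shared oracles and printed reference matrices used across test files.

# Published 4x4 covariance of the degrees conditional proportions
# (2-significant-figure printing).
printed_degrees_sigma <- function() {
  s <- matrix(0, 4, 4)
  diag(s) <- c(1.4e-4, 3.7e-4, 2.8e-3, 5.2e-3)
  s[2, 1] <- 5.1e-6
  s[3, 1] <- 5.2e-6; s[3, 2] <- 3.9e-6
  s[4, 1] <- 5.8e-6; s[4, 2] <- 6.5e-5; s[4, 3] <- -8.4e-6
  s + t(s) - diag(diag(s))
}

# Published 12x12 adjusted covariance of the gaze marginal probabilities.
printed_gaze_sigma <- function() {
  lt <- list(
    c(1.8e-6),
    c(6.2e-7, 1.5e-6),
    c(0, 0, 3.2e-7),
    c(0, 0, 0, 3.2e-7),
    c(-1.1e-6, -2.9e-7, 0, 0, 2.8e-5),
    c(-5.8e-7, -4.9e-7, 0, 0, 6.7e-6, 2.6e-5),
    c(-2.6e-7, -4.2e-7, 0, 0, -6.4e-6, -3.1e-7, 1.3e-5),
    c(-2.3e-7, -2.5e-7, 0, 0, -1.5e-6, -5.3e-6, 4.0e-7, 1.2e-5),
    c(-1.4e-8, -4.6e-8, 0, 0, -2.2e-7, -2.1e-7, 2.8e-8, -2.0e-7, 7.2e-7),
    c(-5.6e-8, -5.5e-9, 0, 0, -2.0e-8, -1.8e-7, -3.1e-8, -6.2e-8, 2.4e-7,
      4.5e-7),
    c(1.6e-8, -1.0e-8, 0, 0, -1.2e-8, -1.1e-7, 3.9e-8, -9.0e-8, 8.9e-9,
      5.4e-8, 3.2e-7),
    c(-1.8e-8, -2.2e-8, 0, 0, -2.4e-7, -2.3e-7, -1.5e-8, -1.2e-7, 1.6e-7,
      -1.2e-9, -7.4e-9, 4.2e-7))
  s <- matrix(0, 12, 12)
  for (i in 1:12) s[i, seq_len(i)] <- lt[[i]]
  s + t(s) - diag(diag(s))
}

# Published fit/penalty table rows for the two applications:
# loglik, penalty, value, weight.
printed_degrees_rows <- function() {
  data.frame(label = c("H1", "H2", "H3", "Hu"),
             loglik = c(9.214, 9.694, 8.544, 10.267),
             penalty = c(2.584, 2.505, 2.182, 4.000),
             gorica = c(-13.261, -14.377, -12.724, -12.535),
             weight = c(0.238, 0.415, 0.182, 0.165))
}

printed_gaze_rows <- function() {
  data.frame(label = c("H1", "H2", "H3", "H4", "Hu"),
             loglik = c(67.228, 68.654, 59.779, 61.481, 68.654),
             penalty = c(9.983, 10.044, 8.000, 8.000, 12.000),
             gorica = c(-114.490, -117.220, -103.559, -106.96, -113.308),
             weight = c(0.182, 0.712, 0.001, 0.004, 0.101))
}

# Independent zoom-in grid minimizer of the Mahalanobis distance over a
# constrained region (K <= 3), used as the projection oracle.
grid_projection_oracle <- function(eta_hat, sigma, S, s, R, r,
                                   lower = NULL, upper = NULL,
                                   rounds = 9L, pts = 15L) {
  K <- length(eta_hat)
  W <- solve(sigma)
  if (is.null(lower)) lower <- eta_hat - 4 * sqrt(max(diag(sigma))) - 1
  if (is.null(upper)) upper <- eta_hat + 4 * sqrt(max(diag(sigma))) + 1
  lower <- rep_len(lower, K)
  upper <- rep_len(upper, K)
  best <- NULL
  for (rd in seq_len(rounds)) {
    grids <- lapply(seq_len(K), function(k) {
      seq(lower[k], upper[k], length.out = pts)
    })
    G <- as.matrix(expand.grid(grids))
    feas <- rep(TRUE, nrow(G))
    if (!is.null(S) && nrow(S)) {
      step <- (upper[1] - lower[1]) / (pts - 1)
      feas <- feas & apply(abs(S %*% t(G) - s), 2, max) <= step
    }
    if (!is.null(R) && nrow(R)) {
      feas <- feas & apply(R %*% t(G) - r, 2, min) >= -1e-12
    }
    if (!any(feas)) {
      # widen until a feasible grid point appears
      lower <- lower - (upper - lower)
      upper <- upper + (upper - lower) / 2
      next
    }
    Gf <- G[feas, , drop = FALSE]
    qf <- rowSums((Gf %*% W) * Gf) - 2 * drop(Gf %*% W %*% eta_hat)
    i <- which.min(qf)
    best <- Gf[i, ]
    span <- (upper - lower) / (pts - 1)
    lower <- best - 1.5 * span
    upper <- best + 1.5 * span
  }
  # polish equality rows exactly by projecting in the W metric
  if (!is.null(S) && nrow(S)) {
    C <- S
    G2 <- C %*% sigma %*% t(C)
    best <- best - sigma %*% t(C) %*% solve(G2, C %*% best - s)
    best <- drop(best)
  }
  best
}

# bivariate-normal positive-orthant probability, closed form
orthant_prob <- function(rho) 0.25 + asin(rho) / (2 * pi)
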