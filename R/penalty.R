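# The GORICA penalty: the expected number of free parameters under the
# hypothesis, PT = sum_l l * LP_l, where the level probabilities LP_l are
# the probabilities that a draw from the zero-mean normal null N(0, Sigma)
# projects onto the constraint cone with exactly l parameters left free
# (l = K - rank of the constraint rows active at the projection).
#
# Hypotheses are relocated (constants zeroed) before sampling, which makes
# the feasible region a closed convex cone and the penalty invariant to
# scaling of Sigma. The bounded-simplex mode deliberately does NOT relocate:
# it exists to quantify how penalties computed directly on bounded cell
# probabilities depend on the null mean and the covariance scale.

new_penalty_result <- function(level_probs, pt, mc_se, T, seed, mode) {
  K <- length(level_probs) - 1L
  names(level_probs) <- paste0("LP", 0:K)
  structure(list(level_probs = level_probs, pt = pt, mc_se = mc_se,
                 T = T, seed = seed, mode = mode),
            class = "penalty_result")
}

#' @export
print.penalty_result <- function(x, ...) {
  cat("Penalty (", x$mode, "): PT = ", round(x$pt, 4), sep = "")
  if (is.finite(x$mc_se) && x$mc_se > 0) {
    cat(" (MC se ", signif(x$mc_se, 2), ", T = ", x$T, ")", sep = "")
  }
  cat("\n  level probabilities: ",
      paste(names(x$level_probs), round(x$level_probs, 3), sep = "=",
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Closed-form penalty for unconstrained and equality-only hypotheses
#'
#' The unconstrained hypothesis has penalty `K` (every draw leaves all K
#' parameters free); a hypothesis with only equality constraints has penalty
#' `K - rank(S)` (every draw projects onto the same linear subspace). For
#' hypotheses with inequality constraints the level distribution is not
#' degenerate and `NULL` is returned; fall back to [penalty_mc()].
#'
#' @param h a [parse_hypothesis()] result.
#' @param K number of parameters (defaults to `length(h$eta_names)`).
#' @return a `penalty_result` with `mc_se = 0`, or `NULL`.
#' @export
penalty_closed_form <- function(h, K = length(h$eta_names)) {
  stopifnot(inherits(h, "linear_hypothesis"))
  if (nrow(h$R) > 0) return(NULL)
  level <- K - .qr_rank(h$S)
  lp <- numeric(K + 1L)
  lp[level + 1L] <- 1
  new_penalty_result(lp, pt = level, mc_se = 0, T = 0L, seed = NULL,
                     mode = "closed_form")
}

#' Monte-Carlo penalty via level probabilities
#'
#' Draws `T` samples from \eqn{N(0, \Sigma)}, projects each onto the
#' relocated constraint cone \eqn{\{S\eta = 0, R\eta \ge 0\}} in the
#' \eqn{\Sigma^{-1}} metric, and counts the level (K minus the rank of the
#' constraint rows active at the projection). `pt` is the mean level and
#' `mc_se` its Monte-Carlo standard error.
#'
#' @param h a [parse_hypothesis()] result (relocated internally).
#' @param sigma positive-definite K x K covariance.
#' @param T number of samples (default 10000; below 1000 a warning notes the
#'   Monte-Carlo error).
#' @param seed RNG seed (recorded; `NULL` leaves the RNG state untouched).
#' @param tol_active activity tolerance on constraint residuals.
#' @return a `penalty_result` with the full level-probability vector.
#' @examples
#' h <- parse_hypothesis("x1 > 0; x2 > 0", c("x1", "x2"), "H1")
#' penalty_mc(h, diag(2), T = 5000, seed = 1)  # PT near 1
#' @export
penalty_mc <- function(h, sigma, T = 10000L, seed = NULL,
                       tol_active = 1e-8) {
  stopifnot(inherits(h, "linear_hypothesis"))
  sigma <- as.matrix(sigma)
  K <- length(h$eta_names)
  stopifnot(nrow(sigma) == K)
  if (!.is_pd(sigma)) stop("covariance matrix is not positive definite")
  cf <- penalty_closed_form(h, K)
  if (!is.null(cf)) return(cf)
  if (T < 1000) warning("T < 1000: the Monte-Carlo error of the penalty ",
                        "may be substantial")
  if (!is.null(seed)) set.seed(seed)
  hr <- relocate(h)
  Z <- t(MASS::mvrnorm(T, mu = rep(0, K), Sigma = sigma))
  pr <- project_polyhedron(Z, sigma, hr$S, hr$s, hr$R, hr$r,
                           tol = tol_active)
  lev <- .levels_from_residuals(pr$proj, hr$S, hr$R, hr$r, K,
                                tol = tol_active)
  lp <- tabulate(lev + 1L, nbins = K + 1L) / T
  pt <- mean(lev)
  new_penalty_result(lp, pt = pt, mc_se = stats::sd(lev) / sqrt(T),
                     T = as.integer(T), seed = seed, mode = "eta")
}

# ---------------------------------------------------------------------------
# Bounded-simplex penalty on cell probabilities

#' Configuration for the bounded-simplex penalty
#'
#' @param mu null-mean vector over the D-1 free cell probabilities; default
#'   `1/D` per cell (the center of the simplex, each cell equally likely).
#' @param c covariance scale factor (> 0).
#' @param T Monte-Carlo samples (default 2000; the non-linear projection
#'   dominates the cost).
#' @param tol_active activity tolerance, scaled internally by `sqrt(c)`.
#' @param starts multistart count for the non-linear projection.
#' @return a `bounded_penalty_config` list.
#' @export
bounded_penalty_config <- function(mu = NULL, c = 1, T = 2000L,
                                   tol_active = 1e-6, starts = 3L) {
  stopifnot(c > 0, T >= 1, starts >= 1)
  structure(list(mu = mu, c = c, T = as.integer(T),
                 tol_active = tol_active, starts = as.integer(starts)),
            class = "bounded_penalty_config")
}

#' Constraint system on cell probabilities
#'
#' Combines a reparameterization and a linear hypothesis on its components
#' into a (generally non-linear) constraint system on the cell probabilities
#' themselves, for use with [penalty_bounded_pi()]. With `spec = NULL` (or
#' an all-sum spec) the system is linear in the cells.
#'
#' @param dims table dims.
#' @param spec an [eta_spec], or `NULL` for no constraints beyond the
#'   simplex bounds (the bounded unconstrained hypothesis).
#' @param h a [parse_hypothesis()] result over `spec$names`, or `NULL`.
#' @return object of class `pi_hypothesis`.
#' @export
pi_hypothesis <- function(dims, spec = NULL, h = NULL) {
  if (!is.null(spec)) stopifnot(inherits(spec, "eta_spec"))
  if (!is.null(h)) {
    stopifnot(inherits(h, "linear_hypothesis"), !is.null(spec))
    if (!identical(h$eta_names, spec$names)) {
      stop("hypothesis names do not match the spec component names")
    }
  }
  structure(list(dims = as.integer(dims), spec = spec, h = h),
            class = "pi_hypothesis")
}

# value and gradient (w.r.t. the full pi vector) of each eta component
.eta_val_grad <- function(spec, pi_full) {
  D <- length(pi_full)
  K <- length(spec$terms)
  vals <- numeric(K)
  grads <- matrix(0, K, D)
  eps <- 1e-12
  for (k in seq_len(K)) {
    tm <- spec$terms[[k]]
    if (tm$type == "sum") {
      vals[k] <- sum(pi_full[tm$a])
      grads[k, tm$a] <- 1
    } else if (tm$type == "ratio") {
      num <- sum(pi_full[tm$a]); den <- sum(pi_full[tm$b]) + eps
      vals[k] <- num / den
      grads[k, tm$a] <- grads[k, tm$a] + 1 / den
      grads[k, tm$b] <- grads[k, tm$b] - num / den^2
    } else {
      Sa <- sum(pi_full[tm$a]) + eps; Sb <- sum(pi_full[tm$b]) + eps
      Sc <- sum(pi_full[tm$c]) + eps; Sd <- sum(pi_full[tm$d]) + eps
      v <- (Sa * Sb) / (Sc * Sd)
      vals[k] <- v
      grads[k, tm$a] <- grads[k, tm$a] + v / Sa
      grads[k, tm$b] <- grads[k, tm$b] + v / Sb
      grads[k, tm$c] <- grads[k, tm$c] - v / Sc
      grads[k, tm$d] <- grads[k, tm$d] - v / Sd
    }
  }
  list(vals = vals, grads = grads)
}

# constraint values/gradients in the free coordinates x (pi_D = 1 - sum x):
# returns eq (values, grads) and ineq (values, grads), gradients row-wise
.pi_constraints <- function(hp, x) {
  d <- length(x)
  pi_full <- c(x, 1 - sum(x))
  out <- list(eq_val = numeric(0), eq_grad = matrix(0, 0, d),
              in_val = numeric(0), in_grad = matrix(0, 0, d))
  if (is.null(hp$spec) || is.null(hp$h)) return(out)
  eg <- .eta_val_grad(hp$spec, pi_full)
  gx <- eg$grads[, seq_len(d), drop = FALSE] - eg$grads[, d + 1L]
  h <- hp$h
  if (nrow(h$S)) {
    out$eq_val <- drop(h$S %*% eg$vals) - h$s
    out$eq_grad <- h$S %*% gx
  }
  if (nrow(h$R)) {
    out$in_val <- drop(h$R %*% eg$vals) - h$r
    out$in_grad <- h$R %*% gx
  }
  out
}

.spec_is_linear <- function(spec) {
  is.null(spec) ||
    all(vapply(spec$terms, `[[`, "", "type") == "sum")
}

# augmented-Lagrangian projection of z onto the bounded feasible set,
# metric W; returns list(x, ok)
.auglag_project <- function(z, W, hp, d, starts = 3L, tol_feas = 1e-8) {
  # inequalities: bounds x_i >= 0, 1 - sum(x) >= 0, and the hypothesis rows
  viol <- function(cs, x) {
    max(c(0, -x, sum(x) - 1,
          if (length(cs$eq_val)) abs(cs$eq_val),
          -cs$in_val))
  }
  fscale <- max(1, max(abs(diag(W))))
  objective <- function(x, lam_eq, lam_in, lam_b, rho) {
    cs <- .pi_constraints(hp, x)
    b_val <- c(x, 1 - sum(x))
    f <- sum((x - z) * (W %*% (x - z)))
    pen <- 0
    if (length(cs$eq_val)) {
      pen <- pen + sum(lam_eq * cs$eq_val) + rho / 2 * sum(cs$eq_val^2)
    }
    sl_in <- pmax(0, lam_in / rho - cs$in_val)
    sl_b <- pmax(0, lam_b / rho - b_val)
    pen <- pen + rho / 2 * (sum(sl_in^2) + sum(sl_b^2))
    f + pen
  }
  gradient <- function(x, lam_eq, lam_in, lam_b, rho) {
    cs <- .pi_constraints(hp, x)
    b_val <- c(x, 1 - sum(x))
    g <- 2 * drop(W %*% (x - z))
    if (length(cs$eq_val)) {
      g <- g + drop(t(cs$eq_grad) %*% (lam_eq + rho * cs$eq_val))
    }
    sl_in <- pmax(0, lam_in / rho - cs$in_val)
    if (length(sl_in) && any(sl_in > 0)) {
      g <- g - drop(t(cs$in_grad) %*% (rho * sl_in))
    }
    sl_b <- pmax(0, lam_b / rho - b_val)
    if (any(sl_b > 0)) {
      gb <- rho * sl_b
      g <- g - gb[seq_len(d)] + sum(gb[d + 1L])
    }
    g
  }
  inits <- list(pmin(pmax(z, 1e-4), 1 - 1e-4))
  s0 <- sum(inits[[1]])
  if (s0 >= 1) inits[[1]] <- inits[[1]] / (s0 + 1e-3)
  ctr <- rep(1 / (d + 1), d)
  inits[[2]] <- ctr
  # where the segment from the simplex center towards z leaves the simplex:
  # a start near the face visible from z, close to the projection of far
  # samples
  dir <- z - ctr
  tmax <- 1
  neg <- dir < 0
  if (any(neg)) tmax <- min(tmax, min(-ctr[neg] / dir[neg]))
  if (sum(dir) > 0) tmax <- min(tmax, (1 - sum(ctr)) / sum(dir))
  inits[[3]] <- ctr + 0.999 * tmax * dir
  if (starts > 3L) {
    for (q in seq_len(starts - 3L)) {
      inits[[3L + q]] <- (inits[[1]] + q * ctr) / (1 + q)
    }
  }
  best <- NULL
  for (x0 in inits[seq_len(min(starts, length(inits)))]) {
    cs0 <- .pi_constraints(hp, x0)
    lam_eq <- rep(0, length(cs0$eq_val))
    lam_in <- rep(0, length(cs0$in_val))
    lam_b <- rep(0, d + 1L)
    rho <- fscale
    x <- x0
    for (outer in seq_len(20L)) {
      op <- stats::optim(x, objective, gradient, method = "BFGS",
                         lam_eq = lam_eq, lam_in = lam_in, lam_b = lam_b,
                         rho = rho,
                         control = list(maxit = 200, reltol = 1e-12))
      x <- op$par
      cs <- .pi_constraints(hp, x)
      v <- viol(cs, x)
      if (v < tol_feas) break
      b_val <- c(x, 1 - sum(x))
      if (length(lam_eq)) lam_eq <- lam_eq + rho * cs$eq_val
      if (length(lam_in)) lam_in <- pmax(0, lam_in - rho * cs$in_val)
      lam_b <- pmax(0, lam_b - rho * b_val)
      rho <- rho * 5
    }
    cs <- .pi_constraints(hp, x)
    if (viol(cs, x) < 10 * tol_feas) {
      f <- sum((x - z) * (W %*% (x - z)))
      if (is.null(best) || f < best$f) best <- list(x = x, f = f)
    }
  }
  if (is.null(best)) return(list(x = rep(NA_real_, d), ok = FALSE))
  list(x = best$x, ok = TRUE)
}

# level of a feasible point: d - rank(active constraint gradients)
.bounded_level <- function(hp, x, tol_act) {
  d <- length(x)
  cs <- .pi_constraints(hp, x)
  rows <- cs$eq_grad
  act_b <- which(x <= tol_act)
  if (length(act_b)) rows <- rbind(rows, diag(d)[act_b, , drop = FALSE])
  if (1 - sum(x) <= tol_act) rows <- rbind(rows, rep(-1, d))
  if (length(cs$in_val)) {
    act_i <- which(abs(cs$in_val) <= tol_act)
    if (length(act_i)) rows <- rbind(rows, cs$in_grad[act_i, , drop = FALSE])
  }
  d - .qr_rank(rows)
}

#' Bounded-simplex penalty on cell probabilities
#'
#' Computes the penalty for a hypothesis stated directly on the bounded cell
#' probabilities (\eqn{0 \le \pi \le 1}, \eqn{\sum \pi = 1}), working in the
#' D-1 free coordinates with the last cell implied. Samples are drawn from
#' \eqn{N(\mu, c\,\Sigma_{\hat\pi})}; feasible samples count at their full
#' level, infeasible ones are projected onto the feasible set (exactly, by
#' active-set enumeration, when the system is linear in the cells; by an
#' augmented-Lagrangian minimizer of the Mahalanobis distance with
#' multistart otherwise), and the level is D-1 minus the rank of the active
#' constraint gradients, bounds included.
#'
#' Because the bounded feasible region is not a (relocated) closed convex
#' cone, this penalty depends on both `mu` and `c`; it is provided to make
#' that dependence measurable. Reparameterizing into unbounded components
#' and using [penalty_mc()] removes the dependence.
#'
#' @param h_pi a [pi_hypothesis()].
#' @param sigma_pi covariance of the cell-probability estimates: D x D (the
#'   leading (D-1) x (D-1) block is used) or (D-1) x (D-1).
#' @param cfg a [bounded_penalty_config()].
#' @param seed RNG seed.
#' @return a `penalty_result` with mode `"bounded_pi"`.
#' @export
penalty_bounded_pi <- function(h_pi, sigma_pi, cfg = bounded_penalty_config(),
                               seed = NULL) {
  stopifnot(inherits(h_pi, "pi_hypothesis"),
            inherits(cfg, "bounded_penalty_config"))
  D <- prod(h_pi$dims)
  d <- D - 1L
  sigma_pi <- as.matrix(sigma_pi)
  if (nrow(sigma_pi) == D) sigma_pi <- sigma_pi[seq_len(d), seq_len(d)]
  stopifnot(nrow(sigma_pi) == d)
  mu <- if (is.null(cfg$mu)) rep(1 / D, d) else cfg$mu
  stopifnot(length(mu) == d, all(mu > 0), sum(mu) < 1)
  Sm <- cfg$c * sigma_pi
  Sm <- (Sm + t(Sm)) / 2
  if (!.is_pd(Sm)) stop("cell-probability covariance is not positive definite")
  if (!is.null(seed)) set.seed(seed)
  T <- cfg$T
  Z <- t(MASS::mvrnorm(T, mu = mu, Sigma = Sm))
  tol_act <- cfg$tol_active * sqrt(max(1, cfg$c))
  linear <- .spec_is_linear(h_pi$spec)
  lev <- integer(T)
  dropped <- 0L
  if (linear) {
    # constraint system linear in the free coordinates: exact projection
    Rl <- rbind(diag(d), rep(-1, d))
    rl <- c(rep(0, d), -1)
    Sl <- matrix(0, 0, d); sl <- numeric(0)
    if (!is.null(h_pi$spec) && !is.null(h_pi$h)) {
      A <- matrix(0, length(h_pi$spec$terms), D)
      for (k in seq_along(h_pi$spec$terms)) {
        A[k, h_pi$spec$terms[[k]]$a] <- 1
      }
      Ax <- A[, seq_len(d), drop = FALSE] - A[, D]
      cst <- A[, D]
      h <- h_pi$h
      if (nrow(h$S)) {
        Sl <- h$S %*% Ax
        sl <- h$s - drop(h$S %*% cst)
      }
      if (nrow(h$R)) {
        Rl <- rbind(Rl, h$R %*% Ax)
        rl <- c(rl, h$r - drop(h$R %*% cst))
      }
    }
    pr <- project_polyhedron(Z, Sm, Sl, sl, Rl, rl, tol = 1e-9,
                             enum_max = 14L)
    X <- pr$proj
    act <- rbind(abs(Sl %*% X - sl) <= tol_act,
                 abs(Rl %*% X - rl) <= tol_act)
    M <- rbind(Sl, Rl)
    keys <- apply(act, 2L, function(cl) paste(which(cl), collapse = ","))
    for (key in unique(keys)) {
      rows <- if (key == "") integer(0) else
        as.integer(strsplit(key, ",")[[1]])
      lev[keys == key] <- d - .qr_rank(M[rows, , drop = FALSE])
    }
  } else {
    W <- solve(Sm)
    for (i in seq_len(T)) {
      x <- Z[, i]
      cs <- .pi_constraints(h_pi, x)
      feasible <- all(x >= 0) && sum(x) <= 1 &&
        (!length(cs$eq_val) || max(abs(cs$eq_val)) <= tol_act) &&
        (!length(cs$in_val) || min(cs$in_val) >= -tol_act)
      if (!feasible) {
        pj <- .auglag_project(x, W, h_pi, d, starts = cfg$starts)
        if (!pj$ok) {
          dropped <- dropped + 1L
          lev[i] <- NA_integer_
          next
        }
        x <- pj$x
      }
      lev[i] <- .bounded_level(h_pi, x, tol_act)
    }
    if (dropped > 0) {
      if (dropped / T > 0.01) {
        stop("more than 1% of samples failed the non-linear projection (",
             dropped, "/", T, ")")
      }
      warning(dropped, " sample(s) dropped after projection failure")
      lev <- lev[!is.na(lev)]
    }
  }
  lp <- tabulate(lev + 1L, nbins = d + 1L) / length(lev)
  new_penalty_result(lp, pt = mean(lev),
                     mc_se = stats::sd(lev) / sqrt(length(lev)),
                     T = T, seed = seed, mode = "bounded_pi")
}

#' Serialize a penalty result to JSON
#' @param p a `penalty_result`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
penalty_to_json <- function(p, path = NULL) {
  obj <- list(mode = p$mode, pt = p$pt, mc_se = p$mc_se, T = p$T,
              seed = p$seed, level_probs = as.list(p$level_probs))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
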