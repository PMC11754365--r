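# Order-restricted estimation under the multivariate-normal approximation:
# eta_tilde = argmin (eta - eta_hat)' Sigma^-1 (eta - eta_hat)
#             s.t. S eta = s, R eta >= r.
# The projection is computed exactly by enumerating candidate active sets of
# the inequality rows: for each subset the equality-constrained projection is
# closed-form, and the KKT conditions (dual feasibility of the multipliers,
# primal feasibility of the inactive rows) identify the solution. With h_r
# inequality rows this costs 2^h_r linear solves, each shared across all
# samples, which is fast for the small constraint systems that arise here; a
# cyclic Dykstra projection is the fallback for large systems.

.qr_rank <- function(M, tol = 1e-9) {
  if (is.null(M) || !length(M)) return(0L)
  qr(M, tol = tol)$rank
}

# independent rows of M (for projection); original M kept for rank counts
.independent_rows <- function(M, tol = 1e-9) {
  if (!nrow(M)) return(integer(0))
  q <- qr(t(M), tol = tol)
  q$pivot[seq_len(q$rank)]
}

# Project columns of Z onto {x : S x = s, R x >= r} in the metric Sigma^-1.
# Returns list(proj = K x n, iterations = NULL). tol: feasibility tolerance.
project_polyhedron <- function(Z, Sigma, S, s, R, r,
                               tol = 1e-8, enum_max = 12L) {
  K <- nrow(Z)
  n <- ncol(Z)
  if (is.null(S)) { S <- matrix(0, 0, K); s <- numeric(0) }
  if (is.null(R)) { R <- matrix(0, 0, K); r <- numeric(0) }
  hr <- nrow(R)
  # reduce S to independent rows; check consistency
  if (nrow(S)) {
    ir <- .independent_rows(S)
    if (length(ir) < nrow(S)) {
      if (.qr_rank(cbind(S, s)) > .qr_rank(S)) {
        stop("inconsistent equality constraints (infeasible system)")
      }
      S <- S[ir, , drop = FALSE]; s <- s[ir]
    }
  }
  if (hr > enum_max) {
    proj <- vapply(seq_len(n), function(i) {
      .dykstra_project(Z[, i], Sigma, S, s, R, r, tol = tol)
    }, numeric(K))
    return(list(proj = matrix(proj, nrow = K)))
  }
  proj <- matrix(NA_real_, K, n)
  assigned <- rep(FALSE, n)
  subsets <- 0:(2^hr - 1L)
  # visit small active sets first: unconstrained interior solutions are common
  sizes <- vapply(subsets, function(b) sum(bitwAnd(b, 2^(seq_len(hr) - 1L)) > 0),
                  numeric(1))
  for (b in subsets[order(sizes)]) {
    if (all(assigned)) break
    act <- which(bitwAnd(b, 2^(seq_len(hr) - 1L)) > 0)
    C <- rbind(S, R[act, , drop = FALSE])
    d <- c(s, r[act])
    m <- nrow(C)
    todo <- which(!assigned)
    if (m == 0L) {
      ok <- rep(TRUE, length(todo))
      if (hr) {
        res <- R %*% Z[, todo, drop = FALSE] - r
        ok <- colSums(res < -tol) == 0L
      }
      hit <- todo[ok]
      proj[, hit] <- Z[, hit]
      assigned[hit] <- TRUE
      next
    }
    if (.qr_rank(C) < m) next
    G <- C %*% Sigma %*% t(C)
    Gi <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Gi)) next
    CZ <- C %*% Z[, todo, drop = FALSE] - d   # m x length(todo)
    lam <- -2 * (Gi %*% CZ)                   # KKT multipliers
    X <- Z[, todo, drop = FALSE] - Sigma %*% t(C) %*% (Gi %*% CZ)
    ok <- rep(TRUE, length(todo))
    if (length(act)) {
      ineq_rows <- nrow(S) + seq_along(act)
      ok <- ok & colSums(lam[ineq_rows, , drop = FALSE] < -tol) == 0L
    }
    inact <- setdiff(seq_len(hr), act)
    if (length(inact)) {
      res <- R[inact, , drop = FALSE] %*% X - r[inact]
      ok <- ok & colSums(res < -tol) == 0L
    }
    hit <- todo[ok]
    if (length(hit)) {
      proj[, hit] <- X[, ok, drop = FALSE]
      assigned[hit] <- TRUE
    }
  }
  if (!all(assigned)) {
    for (i in which(!assigned)) {
      proj[, i] <- .dykstra_project(Z[, i], Sigma, S, s, R, r, tol = tol)
    }
  }
  list(proj = proj)
}

# cyclic Dykstra projection onto an intersection of halfspaces/hyperplanes
# in the Sigma^-1 metric; the single-constraint projection is closed-form.
.dykstra_project <- function(z, Sigma, S, s, R, r, tol = 1e-8,
                             max_iter = 20000L) {
  A <- rbind(S, R)
  b <- c(s, r)
  is_eq <- c(rep(TRUE, nrow(S)), rep(FALSE, nrow(R)))
  m <- nrow(A)
  if (!m) return(z)
  scale <- max(1, abs(z), abs(b))
  x <- z
  corr <- matrix(0, length(z), m)
  SigA <- Sigma %*% t(A)              # K x m
  denom <- colSums(t(A) * SigA)       # a' Sigma a per row
  for (it in seq_len(max_iter)) {
    x_old <- x
    for (j in seq_len(m)) {
      y <- x + corr[, j]
      viol <- b[j] - sum(A[j, ] * y)
      if (is_eq[j] || viol > 0) {
        xj <- y + SigA[, j] * (viol / denom[j])
      } else {
        xj <- y
      }
      corr[, j] <- y - xj
      x <- xj
    }
    if (max(abs(x - x_old)) < 1e-12 * scale) break
  }
  res_eq <- if (nrow(S)) max(abs(S %*% x - s)) else 0
  res_in <- if (nrow(R)) max(0, -(min(R %*% x - r))) else 0
  if (res_eq > 1e-6 * scale || res_in > 1e-6 * scale) {
    stop("projection did not converge (constraint system may be infeasible)")
  }
  x
}

# active-row levels from constraint residuals, grouped by activity pattern
# (levels = K - rank of [S; active R rows])
.levels_from_residuals <- function(X, S, R, r, K, tol = 1e-8) {
  n <- ncol(X)
  hr <- if (is.null(R)) 0L else nrow(R)
  base_rank <- .qr_rank(S)
  if (!hr) return(rep(K - base_rank, n))
  res <- abs(R %*% X - r)
  act <- res <= tol
  keys <- apply(act, 2L, function(col) paste(which(col), collapse = ","))
  lev <- integer(n)
  for (key in unique(keys)) {
    rows <- if (key == "") integer(0) else as.integer(strsplit(key, ",")[[1]])
    rk <- .qr_rank(rbind(S, R[rows, , drop = FALSE]))
    lev[keys == key] <- K - rk
  }
  lev
}

.logdet_chol <- function(Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) {
    stop("covariance matrix is not positive definite")
  })
  2 * sum(log(diag(ch)))
}

.get_sigma <- function(est) {
  if (is.list(est) && !is.null(est$sigma_hat)) return(as.matrix(est$sigma_hat))
  as.matrix(est)
}

.get_eta <- function(est) {
  if (is.list(est) && !is.null(est$eta_hat)) {
    eh <- est$eta_hat
    if (is.list(eh) && !is.null(eh$values)) return(eh$values)
    return(eh)
  }
  est
}

#' Log-likelihood of the unconstrained normal approximation
#'
#' The multivariate-normal log-density evaluated at its own mean:
#' \eqn{-\frac{K}{2}\ln(2\pi) - \frac{1}{2}\ln|\hat\Sigma|}. This is the fit
#' term of every hypothesis whose constraints are satisfied at
#' \eqn{\hat\eta}, and of the unconstrained failsafe.
#'
#' @param est an [bootstrap_estimate()] result, or a covariance matrix.
#' @return scalar log-likelihood.
#' @export
unconstrained_loglik <- function(est) {
  Sigma <- .get_sigma(est)
  K <- nrow(Sigma)
  -K / 2 * log(2 * pi) - 0.5 * .logdet_chol(Sigma)
}

#' Order-restricted maximum likelihood under a hypothesis
#'
#' Projects \eqn{\hat\eta} onto the constraint region of `h` in the
#' Mahalanobis metric of \eqn{\hat\Sigma^{-1}} and evaluates the normal
#' log-likelihood there.
#'
#' @param est an [bootstrap_estimate()] result (its adjusted covariance is
#'   used when present), or a list with `eta_hat` values and `sigma_hat`.
#' @param h a [parse_hypothesis()] result over the same parameter names.
#' @param tol feasibility/activity tolerance on constraint residuals.
#' @return object of class `restricted_fit`: `eta_tilde`, `loglik`,
#'   `quad_form` (the Mahalanobis distance), `active` (row indices of
#'   equality rows then inequality rows active at the solution).
#' @export
restricted_mle <- function(est, h, tol = 1e-8) {
  stopifnot(inherits(h, "linear_hypothesis"))
  Sigma <- .get_sigma(est)
  eta <- .get_eta(est)
  if (inherits(est, "estimation_result") &&
      !identical(est$eta_hat$names, h$eta_names)) {
    stop("hypothesis and estimates use different parameter names")
  }
  if (anyNA(eta)) {
    stop("eta_hat contains inestimable components; the order-restricted ",
         "log-likelihood cannot be computed")
  }
  K <- length(eta)
  stopifnot(nrow(Sigma) == K, ncol(h$S) == K || nrow(h$S) == 0,
            ncol(h$R) == K || nrow(h$R) == 0)
  pr <- project_polyhedron(matrix(eta, ncol = 1L), Sigma,
                           h$S, h$s, h$R, h$r, tol = tol)
  eta_tilde <- drop(pr$proj)
  diff <- eta_tilde - eta
  qf <- drop(t(diff) %*% solve(Sigma, diff))
  qf <- max(qf, 0)
  ll <- -K / 2 * log(2 * pi) - 0.5 * .logdet_chol(Sigma) - 0.5 * qf
  act_eq <- seq_len(nrow(h$S))
  act_in <- if (nrow(h$R)) {
    which(abs(h$R %*% eta_tilde - h$r) <= tol)
  } else integer(0)
  structure(list(eta_tilde = stats::setNames(eta_tilde, h$eta_names),
                 loglik = ll, quad_form = qf,
                 active = list(equality = act_eq, inequality = act_in),
                 label = h$label),
            class = "restricted_fit")
}

#' @export
print.restricted_fit <- function(x, ...) {
  cat("Restricted fit ", x$label, ": loglik = ", round(x$loglik, 3),
      ", quad_form = ", signif(x$quad_form, 4), "\n", sep = "")
  print(round(x$eta_tilde, 4))
  invisible(x)
}
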