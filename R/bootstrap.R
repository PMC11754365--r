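# Nonparametric bootstrap of eta = g(pi): point estimates come from the
# observed table, the covariance from multinomial resamples of the n
# observations (equivalent to resampling the individual observations with
# replacement). Replicates in which any component is inestimable are
# discarded and redrawn; zero-variance diagonals caused by sampling zeros
# are repaired afterwards by adjust_covariance().

#' Bootstrap point estimates and covariance of a reparameterization
#'
#' \eqn{\hat\eta} is the observed-table value (components flagged
#' `zero`/`one` enter with their degenerate value); \eqn{\hat\Sigma} is the
#' sample covariance of `B` bootstrap replicate \eqn{\eta} vectors, each
#' computed from counts drawn from a multinomial\eqn{(n, \hat\pi)}.
#'
#' @param table a [contingency_table] with `n > 0`.
#' @param spec an [eta_spec] over the same dims.
#' @param B number of bootstrap replicates (>= 2; default 1000).
#' @param seed RNG seed (recorded in the result; `NULL` leaves the RNG
#'   state untouched).
#' @param discard_ceiling error when more than this fraction of drawn
#'   replicates is inestimable (default 0.5).
#' @return object of class `estimation_result`: `eta_hat` (an `eta_vector`),
#'   `sigma_hat`, `B`, `discarded`, `adjustment` (`"none"` until
#'   [ensure_positive_definite()] is applied), `seed`, `spec`.
#' @examples
#' est <- bootstrap_estimate(load_fixture("degrees"),
#'                           builtin_spec("conditional_row", c(2, 4), row = 2),
#'                           B = 200, seed = 1)
#' round(est$eta_hat$values, 3)
#' @export
bootstrap_estimate <- function(table, spec, B = 1000L, seed = NULL,
                               discard_ceiling = 0.5) {
  stopifnot(inherits(table, "contingency_table"), inherits(spec, "eta_spec"))
  if (table$n <= 0) stop("table has n = 0")
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  pi_hat <- mle_probabilities(table)
  eta_hat <- eta_value(spec, pi_hat)
  K <- length(spec$terms)
  reps <- matrix(NA_real_, K, B)
  filled <- 0L
  discarded <- 0L
  while (filled < B) {
    draw <- max(B - filled, 32L)
    counts <- stats::rmultinom(draw, size = table$n, prob = pi_hat$values)
    P <- counts / table$n
    ev <- eta_value_matrix(spec, P)
    good <- which(colSums(is.na(ev$values)) == 0L)
    discarded <- discarded + (draw - length(good))
    if (discarded / (discarded + B) > discard_ceiling) {
      stop("more than ", round(100 * discard_ceiling),
           "% of bootstrap replicates have inestimable components; ",
           "choose a different reparameterization or pool sparse levels")
    }
    take <- good[seq_len(min(length(good), B - filled))]
    if (length(take)) {
      reps[, filled + seq_along(take)] <- ev$values[, take, drop = FALSE]
      filled <- filled + length(take)
    }
  }
  sigma <- stats::cov(t(reps))
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(spec$names, spec$names)
  structure(list(eta_hat = eta_hat, sigma_hat = sigma, B = as.integer(B),
                 discarded = as.integer(discarded), adjustment = "none",
                 seed = seed, spec = spec),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("Bootstrap estimation (B = ", x$B, ", discarded = ", x$discarded,
      ", adjustment = ", x$adjustment, ")\n", sep = "")
  df <- data.frame(name = x$eta_hat$names,
                   estimate = round(x$eta_hat$values, 4),
                   variance = signif(diag(x$sigma_hat), 3),
                   flag = x$eta_hat$flags)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Repair zero variances caused by sampling zeros
#'
#' Every zero diagonal entry of the covariance matrix is replaced by the
#' minimum (default), mean, or maximum of the strictly positive diagonal
#' entries; the off-diagonal entries of the repaired rows/columns are set to
#' 0. The minimum is the smallest change compatible with the data (small
#' counts have small bootstrap variances); mean and max incorporate more
#' unfounded information but can succeed when min leaves the matrix
#' indefinite.
#'
#' @param sigma symmetric covariance matrix.
#' @param strategy `"min"`, `"mean"`, or `"max"`.
#' @return list with `sigma` (adjusted matrix) and `applied` (`TRUE` when
#'   any diagonal entry was replaced). Idempotent: adjusting an already
#'   adjusted matrix changes nothing.
#' @export
adjust_covariance <- function(sigma, strategy = c("min", "mean", "max")) {
  strategy <- match.arg(strategy)
  sigma <- as.matrix(sigma)
  stopifnot(isSymmetric(sigma, tol = 1e-8))
  d <- diag(sigma)
  zero <- d <= 0
  pos <- d[!zero]
  if (!length(pos)) stop("all diagonal entries are zero: nothing to repair")
  if (!any(zero)) return(list(sigma = sigma, applied = FALSE))
  repl <- switch(strategy, min = min(pos), mean = mean(pos), max = max(pos))
  out <- sigma
  out[zero, ] <- 0
  out[, zero] <- 0
  diag(out)[zero] <- repl
  list(sigma = out, applied = TRUE)
}

.is_pd <- function(sigma, tol_factor = 1e-12) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol_factor * max(diag(sigma))
}

#' Ensure a positive-definite covariance, escalating the repair
#'
#' Applies [adjust_covariance()] with strategy `min`, then `mean`, then
#' `max`, checking positive definiteness after each (smallest eigenvalue
#' greater than `1e-12` times the largest diagonal entry); the first success
#' is returned with its strategy recorded in `$adjustment`.
#'
#' @param result an `estimation_result` (or a bare covariance matrix, in
#'   which case the adjusted matrix is returned with the strategy as an
#'   attribute).
#' @return the result with `sigma_hat` replaced by the repaired matrix and
#'   `adjustment` set to `"none"`, `"min"`, `"mean"`, or `"max"`.
#' @export
ensure_positive_definite <- function(result) {
  sigma <- .get_sigma(result)
  strategies <- c("min", "mean", "max")
  if (all(diag(sigma) > 0) && .is_pd(sigma)) {
    applied <- "none"
    fixed <- sigma
  } else {
    applied <- NULL
    fixed <- NULL
    for (st in strategies) {
      cand <- tryCatch(adjust_covariance(sigma, st),
                       error = function(e) NULL)
      if (!is.null(cand) && .is_pd(cand$sigma)) {
        applied <- st
        fixed <- cand$sigma
        break
      }
    }
    if (is.null(applied)) {
      stop("covariance matrix could not be made positive definite ",
           "(strategies min, mean, max all failed)")
    }
  }
  if (inherits(result, "estimation_result")) {
    result$sigma_hat <- fixed
    result$adjustment <- applied
    return(result)
  }
  structure(fixed, adjustment = applied)
}

#' Serialize an estimation result to JSON
#'
#' Round-trippable record of the estimates, covariance, flags, B, and seed,
#' so the fit/penalty stages can be fed without re-running the bootstrap.
#'
#' @param est an `estimation_result`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
estimation_to_json <- function(est, path = NULL) {
  obj <- list(names = est$eta_hat$names,
              eta_hat = est$eta_hat$values,
              flags = est$eta_hat$flags,
              sigma_hat = est$sigma_hat,
              B = est$B, discarded = est$discarded,
              adjustment = est$adjustment,
              seed = est$seed)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read an estimation result from JSON
#' @param path file path written by [estimation_to_json()].
#' @return an `estimation_result` (without the generating spec).
#' @export
estimation_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  eta_hat <- structure(list(values = as.numeric(obj$eta_hat),
                            flags = as.character(obj$flags),
                            names = as.character(obj$names)),
                       class = "eta_vector")
  sigma <- as.matrix(obj$sigma_hat)
  dimnames(sigma) <- list(obj$names, obj$names)
  structure(list(eta_hat = eta_hat, sigma_hat = sigma,
                 B = as.integer(obj$B), discarded = as.integer(obj$discarded),
                 adjustment = obj$adjustment,
                 seed = obj$seed, spec = NULL),
            class = "estimation_result")
}
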