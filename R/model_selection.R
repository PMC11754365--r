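# GORICA values, weights, and the end-to-end pipeline: bootstrap ->
# covariance repair -> order-restricted fit + penalty per hypothesis ->
# ranked table. GORICA = -2 * loglik + 2 * PT; with equality-only
# hypotheses PT = K - rank(S), so the criterion reduces to AIC under the
# normal approximation.

#' GORICA value
#' @param loglik order-restricted maximum log-likelihood.
#' @param pt penalty.
#' @return `-2 * loglik + 2 * pt` (vectorized).
#' @export
gorica_value <- function(loglik, pt) {
  stopifnot(all(is.finite(loglik)), all(is.finite(pt)))
  -2 * loglik + 2 * pt
}

#' GORICA weights
#'
#' \eqn{w_m \propto \exp(-\mathrm{GORICA}_m / 2)}, normalized to sum to 1
#' (values are shifted by their minimum for numerical stability). The
#' weights quantify the relative support for each hypothesis; ratios of
#' weights are evidence ratios.
#'
#' @param values per-hypothesis GORICA values (>= 2, all finite).
#' @return weights summing to 1.
#' @export
gorica_weights <- function(values) {
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  w <- exp(-0.5 * (values - min(values)))
  w / sum(w)
}

#' Penalty weights
#'
#' \eqn{w^P_m = \exp(-PT_m) / \sum_{m'} \exp(-PT_{m'})}: the Akaike-weight
#' transform applied to penalties alone, used to compare hypothesis
#' complexities across parameterizations.
#'
#' @param pts per-hypothesis penalties.
#' @return weights summing to 1.
#' @export
penalty_weights <- function(pts) {
  stopifnot(all(is.finite(pts)))
  w <- exp(-(pts - min(pts)))
  w / sum(w)
}

#' Evaluate a hypothesis set on a contingency table
#'
#' The full pipeline: bootstrap estimation of the reparameterized
#' parameters and their covariance, covariance repair for sampling zeros,
#' order-restricted fit and penalty per hypothesis (closed form where
#' available, Monte Carlo otherwise), and assembly into a ranked GORICA
#' table. The unconstrained failsafe is appended when the set requests it.
#'
#' @param table a [contingency_table].
#' @param spec an [eta_spec]; its components are the shared parameter
#'   vector of all hypotheses.
#' @param hset a [hypothesis_set()] over `spec$names`.
#' @param B bootstrap replicates (default 1000).
#' @param T penalty Monte-Carlo samples (default 10000).
#' @param seed master seed; the bootstrap uses `seed` and every penalty uses
#'   `seed + 1`, so one pair drives the whole call (recorded in the output).
#'   `NULL` leaves the RNG state untouched (sequential draws).
#' @param adjust covariance repair: `"auto"` (min, then mean, then max,
#'   first positive-definite wins) or a fixed strategy.
#' @return object of class `gorica_table`: a data.frame with one row per
#'   hypothesis (`label`, `loglik`, `penalty`, `gorica`, `weight`,
#'   `penalty_weight`) plus provenance attributes (`B`, `T`, `seed`,
#'   `adjustment`, `best`). Hypotheses tied for the smallest GORICA within
#'   1e-9 are reported as co-best.
#' @examples
#' \donttest{
#' tab <- load_fixture("degrees")
#' sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
#' hs <- read_hypothesis_file(
#'   system.file("extdata", "degrees_hypotheses.txt", package = "goricct"),
#'   sp$names)
#' evaluate_set(tab, sp, hs, B = 200, T = 2000, seed = 1)
#' }
#' @export
evaluate_set <- function(table, spec, hset, B = 1000L, T = 10000L,
                         seed = NULL, adjust = "auto") {
  stopifnot(inherits(hset, "hypothesis_set"))
  if (!identical(hset$hypotheses[[1]]$eta_names, spec$names)) {
    stop("hypothesis set and spec use different parameter names")
  }
  boot_seed <- seed
  pen_seed <- if (is.null(seed)) NULL else seed + 1L
  est <- tryCatch(
    bootstrap_estimate(table, spec, B = B, seed = boot_seed),
    error = function(e) stop("bootstrap stage: ", conditionMessage(e),
                             call. = FALSE))
  if (anyNA(est$eta_hat$values)) {
    stop("estimation stage: eta_hat has inestimable component(s) [",
         paste(est$eta_hat$names[is.na(est$eta_hat$values)], collapse = ", "),
         "]", call. = FALSE)
  }
  est <- tryCatch({
    if (identical(adjust, "auto")) {
      ensure_positive_definite(est)
    } else {
      adj <- adjust_covariance(est$sigma_hat, adjust)
      if (!.is_pd(adj$sigma)) {
        stop("covariance not positive definite under strategy '", adjust, "'")
      }
      est$sigma_hat <- adj$sigma
      est$adjustment <- if (adj$applied) adjust else "none"
      est
    }
  }, error = function(e) stop("covariance stage: ", conditionMessage(e),
                              call. = FALSE))
  hyps <- hset$hypotheses
  if (hset$include_unconstrained) {
    hyps <- c(hyps, list(unconstrained_hypothesis(spec$names)))
  }
  K <- length(spec$names)
  ll0 <- unconstrained_loglik(est)
  rows <- lapply(hyps, function(h) {
    pen <- penalty_closed_form(h, K)
    if (is.null(pen)) {
      pen <- tryCatch(
        penalty_mc(h, est$sigma_hat, T = T, seed = pen_seed),
        error = function(e) stop("penalty stage (", h$label, "): ",
                                 conditionMessage(e), call. = FALSE))
    }
    fit <- if (nrow(h$S) + nrow(h$R) == 0L) {
      list(loglik = ll0, quad_form = 0)
    } else {
      tryCatch(restricted_mle(est, h),
               error = function(e) stop("fit stage (", h$label, "): ",
                                        conditionMessage(e), call. = FALSE))
    }
    data.frame(label = h$label, loglik = fit$loglik, penalty = pen$pt,
               penalty_mc_se = pen$mc_se, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$gorica <- gorica_value(df$loglik, df$penalty)
  df$weight <- if (nrow(df) == 1L) 1 else gorica_weights(df$gorica)
  df$penalty_weight <- penalty_weights(df$penalty)
  best <- df$label[df$gorica <= min(df$gorica) + 1e-9]
  structure(df,
            class = c("gorica_table", "data.frame"),
            B = est$B, T = as.integer(T), seed = seed,
            adjustment = est$adjustment, best = best,
            estimation = est)
}

#' @export
print.gorica_table <- function(x, digits = 3, ...) {
  cat("GORICA evaluation (B = ", attr(x, "B"), ", T = ", attr(x, "T"),
      ", covariance adjustment = ", attr(x, "adjustment"), ")\n", sep = "")
  df <- as.data.frame(x)[, c("label", "loglik", "penalty", "gorica",
                             "weight", "penalty_weight")]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  cat("best: ", paste(attr(x, "best"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a GORICA table report
#'
#' @param gt a `gorica_table`.
#' @param path output path.
#' @param format `"csv"`, `"json"`, or `"text"`.
#' @return `path`, invisibly.
#' @export
write_gorica_table <- function(gt, path, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  df <- as.data.frame(gt)
  meta <- list(B = attr(gt, "B"), T = attr(gt, "T"), seed = attr(gt, "seed"),
               adjustment = attr(gt, "adjustment"), best = attr(gt, "best"))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (format == "json") {
    writeLines(jsonlite::toJSON(list(meta = meta, table = df),
                                auto_unbox = TRUE, digits = NA), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con)
    print(gt)
    sink()
  }
  invisible(path)
}
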