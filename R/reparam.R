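# Reparameterizations eta = g(pi): marginal sums, conditional proportions,
# and odds-ratio families over the cells of a contingency table. Each
# component is built from cell-index sets so that evaluation reduces to sums
# and ratios of cell probabilities, and degeneracy caused by sampling zeros
# is reported through per-component flags rather than errors.

.term_types <- c("sum", "ratio", "oddsratio")

new_term <- function(type, a, b = NULL, c = NULL, d = NULL) {
  stopifnot(type %in% .term_types)
  list(type = type, a = as.integer(a), b = if (!is.null(b)) as.integer(b),
       c = if (!is.null(c)) as.integer(c), d = if (!is.null(d)) as.integer(d))
}

#' Construct a reparameterization specification
#'
#' An `eta_spec` defines a named vector of parameters
#' \eqn{\eta = g(\pi)}, each component a sum, ratio, or cross-product ratio
#' of cell probabilities. Usually created via [builtin_spec()] or
#' [marginal_pattern_spec()]; `eta_spec()` is the low-level constructor for
#' custom components.
#'
#' Term types: `"sum"` (fields `a` = cell set; value \eqn{\sum_a \pi}),
#' `"ratio"` (`a` over `b`; value \eqn{\sum_a \pi / \sum_b \pi}), and
#' `"oddsratio"` (`a`,`b` over `c`,`d`; value
#' \eqn{(\sum_a\pi)(\sum_b\pi) / ((\sum_c\pi)(\sum_d\pi))}).
#'
#' @param kind label for the family (one of `cells`, `marginal`,
#'   `conditional_row`, `conditional_col`, `local_odds_ratio`,
#'   `marginal_odds_ratio`, `conditional_odds_ratio`, `custom_ratio`).
#' @param terms list of terms from `new_term()`-shaped lists.
#' @param names one unique identifier per component.
#' @param dims the table dims the spec is defined over.
#' @return object of class `eta_spec`.
#' @export
eta_spec <- function(kind, terms, names, dims) {
  dims <- as.integer(dims)
  D <- prod(dims)
  if (anyDuplicated(names)) stop("component names must be unique")
  if (length(terms) != length(names)) stop("one name per term required")
  for (tm in terms) {
    if (!tm$type %in% .term_types) stop("unknown term type: ", tm$type)
    cells <- c(tm$a, tm$b, tm$c, tm$d)
    if (any(cells < 1L) || any(cells > D)) {
      stop("term references a cell outside the table dims")
    }
    if (tm$type == "oddsratio" &&
        (length(tm$a) < 1 || length(tm$b) < 1 ||
         length(tm$c) < 1 || length(tm$d) < 1)) {
      stop("odds-ratio terms need four cell sets")
    }
  }
  types <- unique(vapply(terms, `[[`, "", "type"))
  if (length(types) > 1L) {
    warning("eta_spec mixes term types (", paste(types, collapse = ", "),
            "); hypotheses on non-competing parameterizations should not ",
            "share one set")
  }
  structure(list(kind = kind, terms = terms, names = as.character(names),
                 dims = dims),
            class = "eta_spec")
}

#' @export
print.eta_spec <- function(x, ...) {
  cat("eta_spec '", x$kind, "' over a ", paste(x$dims, collapse = " x "),
      " table: ", length(x$terms), " component(s)\n", sep = "")
  cat("  ", paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# all cells whose multi-index matches `pattern` (NA entries are summed over)
.pattern_cells <- function(dims, pattern) {
  stopifnot(length(pattern) == length(dims))
  grids <- lapply(seq_along(dims), function(f) {
    if (is.na(pattern[f])) seq_len(dims[f]) else as.integer(pattern[f])
  })
  grid <- as.matrix(expand.grid(grids))
  sort(apply(grid, 1L, cell_index, dims = dims))
}

#' Spec of marginal sums selected by index patterns
#'
#' Each pattern is a vector with one entry per factor: a level index to fix,
#' or `NA` for a factor to sum over. For example `c(1, 1, NA)` on a 5x5x5
#' table is the marginal probability of levels (1, 1) of the first two
#' factors, summed over the third.
#'
#' @param dims table dims.
#' @param patterns list of patterns.
#' @param names component names; autogenerated from the patterns if `NULL`.
#' @return an [eta_spec] of kind `"marginal"`.
#' @export
marginal_pattern_spec <- function(dims, patterns, names = NULL) {
  terms <- lapply(patterns, function(p) new_term("sum", .pattern_cells(dims, p)))
  if (is.null(names)) {
    names <- vapply(patterns, function(p) {
      paste0("p", paste(ifelse(is.na(p), "_", p), collapse = ""))
    }, "")
  }
  eta_spec("marginal", terms, names, dims)
}

# local odds ratios of a 2-way layout given a function mapping (i, j) to a
# cell set of the full table
.local_or_terms <- function(I, J, cellset) {
  terms <- list()
  nms <- character(0)
  for (i in 2:I) for (j in 2:J) {
    terms[[length(terms) + 1L]] <- new_term(
      "oddsratio",
      a = cellset(i - 1L, j - 1L), b = cellset(i, j),
      c = cellset(i - 1L, j), d = cellset(i, j - 1L))
    nms <- c(nms, paste0("or", i - 1L, j - 1L))
  }
  list(terms = terms, names = nms)
}

#' Built-in reparameterization families
#'
#' Generates the full component family of one of the five restriction
#' classes, in the adjacent-cell convention: local odds ratios use cells
#' \eqn{(i-1, j-1), (i, j)} over \eqn{(i-1, j), (i, j-1)}.
#'
#' @param kind one of `"cells"`, `"marginal"`, `"conditional_row"`,
#'   `"conditional_col"`, `"local_odds_ratio"`, `"marginal_odds_ratio"`,
#'   `"conditional_odds_ratio"`.
#' @param dims table dims. Odds-ratio marginal/conditional kinds need >= 3
#'   factors; the other kinds are defined for 2-way tables.
#' @param axis for `"marginal"`: the factor whose levels index the
#'   components (cells summed over the other factors). For
#'   `"marginal_odds_ratio"`: the factor summed over.
#' @param row for `"conditional_row"`: the fixed row; components are
#'   \eqn{\pi_{rj} / \pi_{+j}} over columns j.
#' @param col for `"conditional_col"`: the fixed column; components are
#'   \eqn{\pi_{ic} / \pi_{i+}} over rows i.
#' @param fix_axis,fix_level for `"conditional_odds_ratio"`: the factor and
#'   level held fixed; components are the local odds ratios of that slice.
#'   One spec is generated per fixed level (call once per level to enumerate).
#' @param drop_last for `"cells"`: drop the last cell, leaving the D-1 free
#'   cell probabilities (avoids the singular covariance induced by the
#'   sum-to-one constraint). Default `TRUE`.
#' @return an [eta_spec].
#' @examples
#' builtin_spec("conditional_row", c(2, 4), row = 2)
#' @export
builtin_spec <- function(kind, dims, axis = NULL, row = NULL, col = NULL,
                         fix_axis = NULL, fix_level = NULL,
                         drop_last = TRUE) {
  dims <- as.integer(dims)
  nf <- length(dims)
  if (kind == "cells") {
    D <- prod(dims)
    keep <- if (drop_last) seq_len(D - 1L) else seq_len(D)
    terms <- lapply(keep, function(k) new_term("sum", k))
    nms <- vapply(keep, function(k) {
      paste0("pi", paste(cell_multi_index(k, dims), collapse = ""))
    }, "")
    return(eta_spec("cells", terms, nms, dims))
  }
  if (kind == "marginal") {
    if (is.null(axis)) axis <- 1L
    stopifnot(axis >= 1L, axis <= nf)
    patterns <- lapply(seq_len(dims[axis]), function(l) {
      p <- rep(NA_integer_, nf); p[axis] <- l; p
    })
    sp <- marginal_pattern_spec(dims, patterns,
                                names = paste0("m", axis, "_", seq_len(dims[axis])))
    sp$kind <- "marginal"
    return(sp)
  }
  if (kind == "conditional_row") {
    if (nf != 2L) stop("conditional_row needs a 2-way table")
    if (is.null(row)) row <- 2L
    terms <- lapply(seq_len(dims[2]), function(j) {
      new_term("ratio",
               a = cell_index(c(row, j), dims),
               b = vapply(seq_len(dims[1]), function(i)
                 cell_index(c(i, j), dims), 1L))
    })
    return(eta_spec("conditional_row", terms,
                    paste0("eta", seq_len(dims[2])), dims))
  }
  if (kind == "conditional_col") {
    if (nf != 2L) stop("conditional_col needs a 2-way table")
    if (is.null(col)) col <- 1L
    terms <- lapply(seq_len(dims[1]), function(i) {
      new_term("ratio",
               a = cell_index(c(i, col), dims),
               b = vapply(seq_len(dims[2]), function(j)
                 cell_index(c(i, j), dims), 1L))
    })
    return(eta_spec("conditional_col", terms,
                    paste0("eta", seq_len(dims[1])), dims))
  }
  if (kind == "local_odds_ratio") {
    if (nf != 2L) stop("local_odds_ratio needs a 2-way table")
    lo <- .local_or_terms(dims[1], dims[2], function(i, j)
      cell_index(c(i, j), dims))
    return(eta_spec("local_odds_ratio", lo$terms, lo$names, dims))
  }
  if (kind == "marginal_odds_ratio") {
    if (nf < 3L) stop("marginal_odds_ratio needs >= 3 factors")
    if (is.null(axis)) stop("specify `axis` (the factor summed over)")
    rem <- setdiff(seq_len(nf), axis)
    if (length(rem) != 2L) {
      stop("marginal_odds_ratio collapses to a 2-way layout; dims must have ",
           "exactly 3 factors")
    }
    lo <- .local_or_terms(dims[rem[1]], dims[rem[2]], function(i, j) {
      p <- rep(NA_integer_, nf); p[rem[1]] <- i; p[rem[2]] <- j
      .pattern_cells(dims, p)
    })
    return(eta_spec("marginal_odds_ratio", lo$terms, lo$names, dims))
  }
  if (kind == "conditional_odds_ratio") {
    if (nf < 3L) stop("conditional_odds_ratio needs >= 3 factors")
    if (is.null(fix_axis) || is.null(fix_level)) {
      stop("specify `fix_axis` and `fix_level`")
    }
    rem <- setdiff(seq_len(nf), fix_axis)
    if (length(rem) != 2L) stop("dims must have exactly 3 factors")
    lo <- .local_or_terms(dims[rem[1]], dims[rem[2]], function(i, j) {
      p <- rep(NA_integer_, nf)
      p[fix_axis] <- as.integer(fix_level); p[rem[1]] <- i; p[rem[2]] <- j
      cell_index(p, dims)
    })
    sp <- eta_spec("conditional_odds_ratio", lo$terms,
                   paste0(lo$names, "_f", fix_level), dims)
    return(sp)
  }
  stop("unknown reparameterization kind: ", kind)
}

# Evaluate all components on a D x B matrix of probability columns.
# Returns values (K x B; NA where inestimable) and flags for column 1 only
# being irrelevant here -- flags are computed vectorized.
eta_value_matrix <- function(spec, P) {
  K <- length(spec$terms)
  B <- ncol(P)
  vals <- matrix(NA_real_, K, B)
  flags <- matrix("ok", K, B)
  csum <- function(set) {
    if (length(set) == 1L) P[set, ] else colSums(P[set, , drop = FALSE])
  }
  for (k in seq_len(K)) {
    tm <- spec$terms[[k]]
    if (tm$type == "sum") {
      v <- csum(tm$a)
      vals[k, ] <- v
      flags[k, v == 0] <- "zero"
      flags[k, v == 1] <- "one"
    } else if (tm$type == "ratio") {
      num <- csum(tm$a); den <- csum(tm$b)
      bad <- den == 0
      v <- ifelse(bad, NA_real_, num / den)
      vals[k, ] <- v
      flags[k, bad] <- "inestimable"
      flags[k, !bad & num == 0] <- "zero"
      flags[k, !bad & num == den] <- "one"
    } else { # oddsratio
      num <- csum(tm$a) * csum(tm$b)
      den <- csum(tm$c) * csum(tm$d)
      bad <- den == 0
      v <- ifelse(bad, NA_real_, num / den)
      vals[k, ] <- v
      flags[k, bad] <- "inestimable"
      flags[k, !bad & num == 0] <- "zero"
    }
  }
  rownames(vals) <- spec$names
  list(values = vals, flags = flags)
}

#' Evaluate a reparameterization on a probability vector
#'
#' Degeneracy caused by empty cells is reported via flags, not errors:
#' `"zero"` (value 0 with a positive denominator), `"one"` (a conditional
#' proportion equal to 1, which has no sampling variation), and
#' `"inestimable"` (denominator 0; no numeric value).
#'
#' @param spec an [eta_spec].
#' @param pi a [probability_vector] over the same dims.
#' @return object of class `eta_vector`: `values` (NA where inestimable),
#'   `flags`, `names`.
#' @examples
#' sp <- builtin_spec("conditional_row", c(2, 4), row = 2)
#' eta_value(sp, mle_probabilities(load_fixture("degrees")))
#' @export
eta_value <- function(spec, pi) {
  stopifnot(inherits(spec, "eta_spec"), inherits(pi, "probability_vector"))
  if (!identical(as.integer(spec$dims), as.integer(pi$dims))) {
    stop("spec and probability vector have different dims")
  }
  ev <- eta_value_matrix(spec, matrix(pi$values, ncol = 1L))
  structure(list(values = drop(ev$values), flags = drop(ev$flags),
                 names = spec$names),
            class = "eta_vector")
}

#' @export
print.eta_vector <- function(x, ...) {
  df <- data.frame(name = x$names, value = round(x$values, 4),
                   flag = x$flags)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a reparameterization spec to YAML
#' @param spec an [eta_spec].
#' @param path optional file; if `NULL`, the YAML string is returned.
#' @return `path` (invisibly) or a YAML string.
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  obj <- list(kind = spec$kind, dims = as.integer(spec$dims),
              names = spec$names,
              terms = lapply(spec$terms, function(tm) {
                Filter(Negate(is.null),
                       list(type = tm$type, a = tm$a, b = tm$b,
                            c = tm$c, d = tm$d))
              }))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a reparameterization spec from YAML
#'
#' Accepts either an explicit spec (kind/dims/names/terms as written by
#' [spec_to_yaml()]) or a builtin description
#' (`kind`, `dims`, plus [builtin_spec()] options such as `row` or `axis`).
#'
#' @param path file path, or a YAML string when `text = TRUE`.
#' @param text interpret `path` as YAML text.
#' @return an [eta_spec].
#' @export
spec_from_yaml <- function(path, text = FALSE) {
  obj <- if (text) yaml::yaml.load(path) else yaml::read_yaml(path)
  if (!is.null(obj$terms)) {
    terms <- lapply(obj$terms, function(tm) {
      new_term(tm$type, tm$a, tm$b, tm$c, tm$d)
    })
    return(eta_spec(obj$kind, terms, unlist(obj$names),
                    unlist(obj$dims)))
  }
  if (!is.null(obj$patterns)) {
    pats <- lapply(obj$patterns, function(p) {
      vapply(p, function(e) {
        if (is.null(e) || (is.character(e) && e %in% c("_", "NA")))
          NA_integer_ else as.integer(e)
      }, integer(1))
    })
    return(marginal_pattern_spec(unlist(obj$dims), pats,
                                 names = unlist(obj$names)))
  }
  do.call(builtin_spec, c(list(kind = obj$kind, dims = unlist(obj$dims)),
                          obj[setdiff(names(obj), c("kind", "dims"))]))
}
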