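# A small text mini-language for (in)equality-constrained hypotheses over a
# named parameter vector, parsed into the linear constraint system
#   H: S eta = s,  R eta > r.
# Supported: +, -, numeric coefficients with optional '*', relations =, >, <,
# chains (a > b > c), and brace fan-out (a > {b, c} expands pairwise).
# Strict inequalities are represented as closed constraints for optimization;
# the feasible boundaries have probability zero under the sampling
# distributions considered here.

# split a string at top-level occurrences of any character in `chars`
# (ignoring characters nested inside braces)
.split_top <- function(txt, chars) {
  out <- character(0)
  depth <- 0L
  cur <- ""
  for (ch in strsplit(txt, "")[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced '}' in: ", txt)
    if (depth == 0L && ch %in% chars) {
      out <- c(out, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  if (depth != 0L) stop("unbalanced '{' in: ", txt)
  c(out, cur)
}

# parse one linear expression into c(coefs, constant)
.parse_linexpr <- function(txt, eta_names) {
  K <- length(eta_names)
  coefs <- numeric(K)
  const <- 0
  s <- gsub("\\s+", "", txt)
  if (s == "") stop("empty expression in hypothesis near '", txt, "'")
  s <- gsub("-", "+-", s, fixed = TRUE)
  pieces <- strsplit(s, "+", fixed = TRUE)[[1]]
  pieces <- pieces[pieces != ""]
  if (!length(pieces)) stop("empty expression in hypothesis near '", txt, "'")
  for (p in pieces) {
    sign <- 1
    if (startsWith(p, "-")) {
      sign <- -1
      p <- substring(p, 2)
    }
    if (p == "") stop("dangling sign in hypothesis near '", txt, "'")
    parts <- strsplit(p, "*", fixed = TRUE)[[1]]
    if (length(parts) > 2L) {
      stop("non-linear term '", p, "' in hypothesis (products of parameters ",
           "are not supported)")
    }
    is_num <- grepl("^[0-9.]+([eE][+-]?[0-9]+)?$", parts)
    if (length(parts) == 2L) {
      if (all(is_num)) {
        const <- const + sign * prod(as.numeric(parts))
        next
      }
      if (!any(is_num)) {
        stop("non-linear term '", p, "' in hypothesis (product of two ",
             "parameter names)")
      }
      coef <- as.numeric(parts[is_num])
      name <- parts[!is_num]
    } else if (is_num) {
      const <- const + sign * as.numeric(parts)
      next
    } else {
      coef <- 1
      name <- parts
    }
    k <- match(name, eta_names)
    if (is.na(k)) {
      stop("unknown parameter name '", name, "' in hypothesis; declared: ",
           paste(eta_names, collapse = ", "))
    }
    coefs[k] <- coefs[k] + sign * coef
  }
  c(coefs, const)
}

# parse one chain segment: either a brace set or a single expression;
# returns a matrix of (coefs, const) rows
.parse_segment <- function(txt, eta_names) {
  s <- trimws(txt)
  if (startsWith(s, "{")) {
    s2 <- trimws(s)
    if (!endsWith(s2, "}")) stop("malformed brace set: ", txt)
    inner <- substr(s2, 2, nchar(s2) - 1L)
    exprs <- .split_top(inner, ",")
  } else {
    exprs <- s
  }
  t(vapply(exprs, .parse_linexpr, numeric(length(eta_names) + 1L),
           eta_names = eta_names))
}

.order_rows <- function(M, v) {
  if (!nrow(M)) return(list(M = M, v = v))
  key <- do.call(order, c(lapply(seq_len(ncol(M)), function(j) M[, j]),
                          list(v)))
  list(M = M[key, , drop = FALSE], v = v[key])
}

#' Parse a textual hypothesis into a linear constraint system
#'
#' Constraint expressions over declared parameter names are turned into
#' \eqn{H: S \eta = s, R \eta > r}. Multiple constraints are separated by
#' `;`, `,` (outside braces), or newlines. `a > {b, c}` expands to the rows
#' `a - b > 0` and `a - c > 0`; chains `a > b > c` expand pairwise; `<` rows
#' are negated into `>` rows; constants are moved to the right-hand side.
#' An empty `text` (or `NULL`) yields the unconstrained hypothesis.
#'
#' @param text constraint expressions.
#' @param eta_names the K parameter names the hypothesis is defined over.
#' @param label hypothesis identifier.
#' @return object of class `linear_hypothesis` with fields `label`, `S`,
#'   `s`, `R`, `r`, `eta_names`. Rows are normalized to lexicographic order
#'   so equivalent texts produce identical systems.
#' @examples
#' parse_hypothesis("eta1 > {eta2, eta3}", c("eta1", "eta2", "eta3"), "H1")
#' @export
parse_hypothesis <- function(text, eta_names, label = "H") {
  K <- length(eta_names)
  S <- matrix(0, 0, K); s <- numeric(0)
  R <- matrix(0, 0, K); r <- numeric(0)
  if (!is.null(text) && !identical(trimws(text), "")) {
    constraints <- .split_top(gsub("\n", ";", text), c(";", ","))
    constraints <- trimws(constraints)
    constraints <- constraints[constraints != ""]
    for (con in constraints) {
      segs <- .split_top(con, c(">", "<", "="))
      ops <- regmatches(con, gregexpr("[<>=]", con))[[1]]
      # collapse '>=', '<=', '==' written with two characters
      keep <- rep(TRUE, length(ops))
      if (length(ops) > 1L) {
        for (q in seq_len(length(ops) - 1L)) {
          if (keep[q] && segs[q + 1L] == "" && ops[q + 1L] == "=") {
            keep[q + 1L] <- FALSE
          }
        }
      }
      segs <- segs[c(keep, TRUE)]
      ops <- ops[keep]
      if (!length(ops)) stop("no relation in constraint: ", con)
      if (any(trimws(segs) == "")) stop("empty side of relation in: ", con)
      mats <- lapply(segs, .parse_segment, eta_names = eta_names)
      for (q in seq_along(ops)) {
        L <- mats[[q]]; Rt <- mats[[q + 1L]]
        for (a in seq_len(nrow(L))) for (b in seq_len(nrow(Rt))) {
          lhs <- L[a, ]; rhs <- Rt[b, ]
          if (ops[q] == "<") { tmp <- lhs; lhs <- rhs; rhs <- tmp }
          row <- lhs[seq_len(K)] - rhs[seq_len(K)]
          cst <- rhs[K + 1L] - lhs[K + 1L]
          if (all(abs(row) < 1e-12)) {
            stop("constraint without parameters in: ", con)
          }
          if (ops[q] == "=") {
            S <- rbind(S, row); s <- c(s, cst)
          } else {
            R <- rbind(R, row); r <- c(r, cst)
          }
        }
      }
    }
  }
  oS <- .order_rows(S, s); oR <- .order_rows(R, r)
  structure(list(label = label, S = unname(oS$M), s = unname(oS$v),
                 R = unname(oR$M), r = unname(oR$v),
                 eta_names = as.character(eta_names)),
            class = "linear_hypothesis")
}

#' The unconstrained (failsafe) hypothesis
#' @param eta_names parameter names.
#' @param label identifier (default `"Hu"`).
#' @return a [parse_hypothesis()] result with no constraints.
#' @export
unconstrained_hypothesis <- function(eta_names, label = "Hu") {
  parse_hypothesis(NULL, eta_names, label)
}

#' Relocate a hypothesis to the origin
#'
#' Returns the homogeneous system (same S and R, constants set to 0) used
#' for penalty computation: shifting the apex of the constraint cone to the
#' origin makes the feasible region a closed convex cone, so the penalty is
#' invariant to the scaling of the covariance matrix.
#'
#' @param h a `linear_hypothesis`.
#' @return the relocated hypothesis.
#' @export
relocate <- function(h) {
  stopifnot(inherits(h, "linear_hypothesis"))
  h$s <- rep(0, length(h$s))
  h$r <- rep(0, length(h$r))
  h
}

.fmt_coef <- function(x) format(x, digits = 15, scientific = FALSE,
                                trim = TRUE)

.render_row <- function(coefs, cst, op, eta_names) {
  parts <- character(0)
  for (k in seq_along(coefs)) {
    ck <- coefs[k]
    if (ck == 0) next
    term <- if (abs(ck) == 1) eta_names[k] else {
      paste0(.fmt_coef(abs(ck)), "*", eta_names[k])
    }
    parts <- c(parts, if (ck < 0) paste0("- ", term) else {
      if (length(parts)) paste0("+ ", term) else term
    })
  }
  paste(paste(parts, collapse = " "), op, .fmt_coef(cst))
}

#' Render a hypothesis back to constraint text
#'
#' `parse_hypothesis(render_hypothesis(h), h$eta_names)` reproduces
#' `(S, s, R, r)` exactly.
#'
#' @param h a `linear_hypothesis`.
#' @return a single string of `;`-separated constraints (empty for the
#'   unconstrained hypothesis).
#' @export
render_hypothesis <- function(h) {
  rows <- c(
    vapply(seq_len(nrow(h$S)), function(q)
      .render_row(h$S[q, ], h$s[q], "=", h$eta_names), ""),
    vapply(seq_len(nrow(h$R)), function(q)
      .render_row(h$R[q, ], h$r[q], ">", h$eta_names), "")
  )
  paste(rows, collapse = "; ")
}

#' @export
print.linear_hypothesis <- function(x, ...) {
  txt <- render_hypothesis(x)
  cat(x$label, ": ", if (txt == "") "(unconstrained)" else txt, "\n", sep = "")
  invisible(x)
}

#' Bundle hypotheses into an ordered set
#'
#' @param ... `linear_hypothesis` objects (or a single list of them).
#' @param include_unconstrained append the unconstrained failsafe when the
#'   set is evaluated (default `TRUE`).
#' @return object of class `hypothesis_set`.
#' @export
hypothesis_set <- function(..., include_unconstrained = TRUE) {
  hyps <- list(...)
  if (length(hyps) == 1L && !inherits(hyps[[1]], "linear_hypothesis")) {
    hyps <- hyps[[1]]
  }
  stopifnot(length(hyps) >= 1L)
  for (h in hyps) stopifnot(inherits(h, "linear_hypothesis"))
  nm0 <- hyps[[1]]$eta_names
  for (h in hyps) {
    if (!identical(h$eta_names, nm0)) {
      stop("all hypotheses in a set must share the same parameter names")
    }
  }
  labels <- vapply(hyps, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("hypothesis labels must be unique")
  structure(list(hypotheses = hyps,
                 include_unconstrained = isTRUE(include_unconstrained)),
            class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  for (h in x$hypotheses) print(h)
  if (x$include_unconstrained) cat("(+ unconstrained failsafe)\n")
  invisible(x)
}

#' Read a hypothesis set from a plain-text file
#'
#' One hypothesis per non-empty line, `label: expr; expr; ...`. Lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @param eta_names parameter names the hypotheses are defined over.
#' @param include_unconstrained passed to [hypothesis_set()].
#' @return a [hypothesis_set()].
#' @export
read_hypothesis_file <- function(path, eta_names,
                                 include_unconstrained = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!length(lines)) stop("no hypotheses in ", path)
  hyps <- lapply(lines, function(ln) {
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 0) stop("expected 'label: constraints' in line: ", ln)
    parse_hypothesis(substring(ln, pos + 1L), eta_names,
                     label = trimws(substring(ln, 1L, pos - 1L)))
  })
  hypothesis_set(hyps, include_unconstrained = include_unconstrained)
}
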