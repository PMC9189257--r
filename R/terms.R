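# Model specifications: ordered predictor terms (plain columns, composites,
# products) and linear restrictions L %*% beta = c on their coefficients.

#' Predictor term constructors
#'
#' A model is an ordered list of labelled predictor terms (the intercept is
#' always present and never listed).  Three kinds of term exist:
#'
#' * `term_col(col)` -- a raw column, optionally mean-centered;
#' * `term_product(a, b)` -- the elementwise product of two columns, with
#'   per-factor centering flags (centering happens *before* the product is
#'   formed, and the product is never re-centered afterwards);
#' * `term_composite(cols, weights)` -- a weighted sum of >= 2 columns
#'   (a cumulative-risk index is the unit-weight special case).
#'
#' Composites and plain columns are linear in the source columns, so models
#' built from them can be fitted from summary moments alone; product terms
#' require raw data (or moments that already include the product column).
#'
#' @param col,a,b,cols Source column name(s).
#' @param label Term label; defaults to a readable derived label.
#' @param center,center_a,center_b Mean-center the column(s) first?
#' @param weights Numeric weights for a composite (recycled; default 1).
#' @return A `cr_term` object.
#' @export
term_col <- function(col, label = col, center = FALSE) {
  new_term(label, kind = "col", cols = col, center = center)
}

#' @rdname term_col
#' @export
term_product <- function(a, b, label = paste0(a, ":", b),
                         center_a = FALSE, center_b = FALSE) {
  new_term(label, kind = "product", cols = c(a, b),
           center = c(center_a, center_b))
}

#' @rdname term_col
#' @export
term_composite <- function(cols, weights = 1, label) {
  if (length(cols) < 2)
    stop_validation("a composite term needs >= 2 source columns")
  weights <- rep_len(as.numeric(weights), length(cols))
  if (any(!is.finite(weights)))
    stop_validation("composite weights must be finite")
  if (missing(label)) label <- paste(cols, collapse = "+")
  new_term(label, kind = "composite", cols = cols, weights = weights)
}

new_term <- function(label, kind, cols, center = FALSE, weights = NULL) {
  structure(list(label = label, kind = kind, cols = cols,
                 center = center, weights = weights),
            class = "cr_term")
}

#' Define a regression model
#'
#' @param outcome Outcome column name.
#' @param terms Predictor terms: a character vector (plain columns) and/or a
#'   list of [term_col]/[term_product]/[term_composite] objects.  May be
#'   empty (intercept-only model).
#' @return A `model_spec` object with uniquely labelled terms.
#' @export
model_spec <- function(outcome, terms = list()) {
  if (is.character(terms)) terms <- lapply(terms, term_col)
  if (inherits(terms, "cr_term")) terms <- list(terms)
  terms <- lapply(terms, function(tm) {
    if (is.character(tm)) tm <- term_col(tm)
    if (!inherits(tm, "cr_term")) stop_validation("invalid term object")
    tm
  })
  labels <- vapply(terms, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop_validation("duplicate term labels: ",
                    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (outcome %in% labels)
    stop_validation("outcome cannot also be a predictor term")
  structure(list(outcome = outcome, terms = terms, labels = labels),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- if (length(x$labels)) paste(x$labels, collapse = " + ") else "1"
  cat("Model: ", x$outcome, " ~ ", rhs, "\n", sep = "")
  invisible(x)
}

#' Define a set of linear restrictions
#'
#' Restrictions are rows of `L %*% beta = c` over the *slope* coefficients of
#' a model's terms (the intercept is never restricted).  Rows must be
#' linearly independent.
#'
#' @param L Numeric matrix, one row per restriction, columns in term order
#'   (or named by term label).
#' @param c Right-hand-side constants (default 0).
#' @param labels Human-readable row labels.
#' @param terms Character vector of term labels the columns refer to.
#' @return A `restriction_set` object.
#' @export
restriction_set <- function(L, c = 0, labels = NULL, terms = colnames(L)) {
  L <- as.matrix(L)
  if (is.null(terms))
    stop_validation("restriction matrix needs term labels (colnames or terms=)")
  colnames(L) <- terms
  q <- nrow(L)
  c <- rep_len(as.numeric(c), q)
  if (is.null(labels)) labels <- paste("Restriction", seq_len(q))
  if (q > 0 && qr(L)$rank < q) {
    # dependent rows: contradictory constants mean an infeasible system,
    # matching constants mean a redundant row
    if (qr(cbind(L, c))$rank > qr(L)$rank)
      stop_validation("restrictions are contradictory (L beta = c has no solution)")
    rk <- vapply(seq_len(q), function(i) qr(L[seq_len(i), , drop = FALSE])$rank,
                 0L)
    bad <- which(rk == c(0L, rk[-q]))[1]
    stop_validation("restriction rows are linearly dependent; row '",
                    labels[bad], "' is redundant")
  }
  structure(list(L = L, c = c, labels = labels, q = q),
            class = "restriction_set")
}

#' Parse restriction strings against a model's term labels
#'
#' The mini-language supports three forms:
#' * equality chains: `"Occ = Educ = Eth = Inter"` expands to q-1 pairwise
#'   rows in declaration order, each written (earlier term) - (later term) = 0;
#' * zero restrictions: `"E = 0"`;
#' * general linear rows: `"3*A - B = 1"`.
#'
#' Term labels are matched case-sensitively.
#'
#' @param strings Character vector of restriction expressions.
#' @param terms Term labels of the model (a `model_spec` is also accepted).
#' @return A [restriction_set].
#' @export
parse_restrictions <- function(strings, terms) {
  if (inherits(terms, "model_spec")) terms <- terms$labels
  rows <- list(); cs <- numeric(); labels <- character()
  for (s in strings) {
    parts <- trimws(strsplit(s, "=", fixed = TRUE)[[1]])
    if (length(parts) < 2)
      stop_validation("restriction '", s, "' has no '='")
    if (length(parts) > 2) {
      # equality chain: every part must be a bare term label
      if (!all(parts %in% terms))
        stop_validation("chain restriction '", s,
                        "' may only contain term labels")
      for (i in seq_len(length(parts) - 1)) {
        w <- stats::setNames(numeric(length(terms)), terms)
        w[parts[i]] <- 1; w[parts[i + 1]] <- -1
        rows[[length(rows) + 1]] <- w
        cs <- c(cs, 0)
        labels <- c(labels, paste(parts[i], "=", parts[i + 1]))
      }
    } else {
      lhs <- parse_linear(parts[1], terms, s)
      rhs <- parse_linear(parts[2], terms, s)
      rows[[length(rows) + 1]] <- lhs$w - rhs$w
      cs <- c(cs, rhs$const - lhs$const)
      labels <- c(labels, s)
    }
  }
  restriction_set(do.call(rbind, rows), cs, labels, terms = terms)
}

# parse "3*A - B + 1" into weights over term labels plus a constant
parse_linear <- function(expr, terms, context) {
  w <- stats::setNames(numeric(length(terms)), terms)
  const <- 0
  # split into signed tokens
  expr <- gsub("-", "+-", gsub("[[:space:]]", "", expr))
  tokens <- strsplit(expr, "+", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    stop_validation("empty side in restriction '", context, "'")
  for (tok in tokens) {
    sign <- 1
    if (startsWith(tok, "-")) { sign <- -1; tok <- substring(tok, 2) }
    if (grepl("*", tok, fixed = TRUE)) {
      bits <- strsplit(tok, "*", fixed = TRUE)[[1]]
      coef <- suppressWarnings(as.numeric(bits[1]))
      if (length(bits) != 2 || is.na(coef) || !(bits[2] %in% terms))
        stop_validation("cannot parse token '", tok, "' in restriction '",
                        context, "'")
      w[bits[2]] <- w[bits[2]] + sign * coef
    } else if (tok %in% terms) {
      w[tok] <- w[tok] + sign
    } else {
      num <- suppressWarnings(as.numeric(tok))
      if (is.na(num))
        stop_validation("unknown term '", tok, "' in restriction '", context,
                        "'; declared terms: ", paste(terms, collapse = ", "))
      const <- const + sign * num
    }
  }
  list(w = w, const = const)
}

#' @export
print.restriction_set <- function(x, ...) {
  cat("Restriction set: q =", x$q, "\n")
  for (i in seq_len(x$q)) {
    w <- x$L[i, ]
    nz <- which(w != 0)
    lhs <- paste(ifelse(w[nz] == 1, "", ifelse(w[nz] == -1, "-",
                                               paste0(w[nz], "*"))),
                 names(w)[nz], sep = "", collapse = " + ")
    lhs <- gsub("\\+ -", "- ", lhs)
    cat(sprintf("  %-24s %s = %g\n", x$labels[i], lhs, x$c[i]))
  }
  invisible(x)
}
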