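# Cumulative-risk composites: building summed indices and verifying the
# identity between "composite as one predictor" and "sources as separate
# predictors under an all-equal restriction".

#' Append a cumulative-risk index column to a dataset
#'
#' The index is the weighted sum of the source indicator columns (unit
#' weights by default, the classic count-of-risks composite).  With
#' `dichotomous = TRUE` every source value must be 0 or 1, so a unit-weight
#' index of k indicators ranges over 0..k.
#'
#' @param data A data frame.
#' @param sources Names of >= 2 source columns.
#' @param weights Numeric weights (recycled; default 1).
#' @param label Name of the appended column.
#' @param dichotomous Require all source values to be in \{0, 1\}?
#' @return `data` with the index appended; provenance (sources, weights) is
#'   recorded in `attr(data[[label]], "provenance")`.
#' @export
build_index <- function(data, sources, weights = 1, label = "CR",
                        dichotomous = FALSE) {
  def <- term_composite(sources, weights, label = label)
  missing_cols <- setdiff(sources, names(data))
  if (length(missing_cols))
    stop_validation("unknown source column(s): ",
                    paste(missing_cols, collapse = ", "))
  X <- as.matrix(data[sources])
  if (!is.numeric(X)) stop_validation("source columns must be numeric")
  if (dichotomous) {
    bad <- which(apply(X, 1, function(r) any(!(r %in% c(0, 1)))))
    if (length(bad))
      stop_validation("dichotomous = TRUE but non-0/1 values in row(s): ",
                      paste(utils::head(bad, 10), collapse = ", "),
                      if (length(bad) > 10) " ..." else "")
  }
  idx <- drop(X %*% def$weights)
  attr(idx, "provenance") <- list(sources = sources, weights = def$weights)
  data[[label]] <- idx
  data
}

#' Dichotomize a quantitative indicator at an explicit cut
#'
#' Provided only as an explicit utility: the cut must be supplied, either as
#' an absolute threshold or as an upper-tail quantile.  Sample-derived cuts
#' (e.g. "top 25 percent of this sample") are sample-specific and hinder
#' cross-study comparison, so a quantile cut emits a warning.
#'
#' @param x Numeric vector.
#' @param threshold Absolute cut: risk = 1 when `x >= threshold`.
#' @param quantile Upper-tail probability: risk = 1 for the top `quantile`
#'   share of the *sample* (warns about sample specificity).
#' @param higher_is_risk If `FALSE`, risk = 1 below the cut instead.
#' @return An integer 0/1 vector.
#' @export
dichotomize_indicator <- function(x, threshold = NULL, quantile = NULL,
                                  higher_is_risk = TRUE) {
  if (is.null(threshold) == is.null(quantile))
    stop_validation("supply exactly one of threshold or quantile")
  if (!is.null(quantile)) {
    warning("quantile cut-points are sample-specific; the resulting ",
            "indicator may not be comparable across studies", call. = FALSE)
    threshold <- stats::quantile(x, 1 - quantile, na.rm = TRUE, names = FALSE)
  }
  out <- if (higher_is_risk) x >= threshold else x <= threshold
  as.integer(out)
}

#' Z-score an indicator within the sample
#'
#' Standardizing to mean 0, SD 1 puts indicators on a common within-sample
#' metric, but the scale is sample-specific: a standardized zero in a
#' high-risk sample is not a standardized zero in a representative one, so
#' cross-study comparability is lost.  The function warns accordingly.
#'
#' @param x Numeric vector.
#' @return `(x - mean)/sd`.
#' @export
standardize_indicator <- function(x) {
  warning("within-sample standardization is sample-specific and can destroy ",
          "comparability across studies", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
}

#' Check composite-versus-constraint equivalence
#'
#' Fits (a) the model with the composite entered as a single predictor and
#' (b) the model with the sources entered separately under an all-equal
#' restriction, and reports the maximum absolute discrepancy over R-squared,
#' SSE, intercept, shared coefficient, shared SE, adjusted R-squared and
#' SBC.  For a unit-weight composite the two fits are algebraically
#' identical; the check passes when the discrepancy is below `tol`.
#' Non-unit weights break the identity and are flagged as intentionally
#' non-equivalent (the discrepancy is still reported).
#'
#' If `interaction_with` is given, both models additionally carry product
#' terms (composite x moderator vs per-source x moderator with matching
#' equality restrictions), which is the gene-by-environment use case.
#'
#' @param x Data input accepted by [fit_ols].
#' @param outcome Outcome column name.
#' @param sources Composite source columns.
#' @param weights Composite weights (default 1).
#' @param covariates Additional plain-column terms in both models.
#' @param interaction_with Optional moderator column; adds composite x
#'   moderator vs per-source product terms under their own equality chain.
#' @param center_moderator Mean-center the moderator before products?
#' @param tol Equivalence tolerance (default 1e-8).
#' @return A `cr_equivalence` report.
#' @export
check_composite_equivalence <- function(x, outcome, sources, weights = 1,
                                        covariates = character(),
                                        interaction_with = NULL,
                                        center_moderator = TRUE,
                                        tol = 1e-8) {
  weights <- rep_len(as.numeric(weights), length(sources))
  unit <- all(weights == weights[1])
  comp_label <- "CRsum"
  cov_terms <- lapply(covariates, term_col)
  # model (a): composite as one predictor
  terms_a <- c(cov_terms,
               list(term_composite(sources, weights, label = comp_label)))
  # model (b): sources entered separately, all-equal restriction
  terms_b <- c(cov_terms, lapply(sources, term_col))
  restr_b <- paste(sources, collapse = " = ")
  if (!is.null(interaction_with)) {
    if (!is.data.frame(x))
      stop_validation("interaction_with requires raw data (product terms ",
                      "cannot be formed from summary moments)")
    x <- build_index(x, sources, weights, label = comp_label)
    mod_term <- term_col(interaction_with, center = center_moderator)
    terms_a <- c(list(mod_term), terms_a,
                 list(term_product(comp_label, interaction_with,
                                   center_b = center_moderator,
                                   label = paste0(comp_label, ":E"))))
    prod_labels <- paste0(sources, ":E")
    prod_terms <- mapply(function(s, lab)
      term_product(s, interaction_with, center_b = center_moderator,
                   label = lab),
      sources, prod_labels, SIMPLIFY = FALSE)
    terms_b <- c(list(mod_term), terms_b, prod_terms)
    restr_b <- c(restr_b, paste(prod_labels, collapse = " = "))
  }
  spec_a <- model_spec(outcome, terms_a)
  spec_b <- model_spec(outcome, terms_b)
  fit_a <- fit_ols(x, spec_a)
  fit_b <- fit_restricted(x, spec_b, restr_b)
  ca <- fit_a$coefficients
  cb <- fit_b$coefficients
  shared_a <- ca[ca$term == comp_label, ]
  shared_b <- cb[cb$term == sources[1], ]
  # the composite coefficient multiplies w_j * X_j; on the per-source side
  # the common slope multiplies X_j directly, so compare on the source scale
  disc <- c(
    r2 = abs(fit_a$r2 - fit_b$r2),
    sse = abs(fit_a$sse - fit_b$sse) / max(1, abs(fit_b$sse)),
    intercept = abs(ca$estimate[1] - cb$estimate[1]),
    coefficient = abs(shared_a$estimate * weights[1] - shared_b$estimate),
    se = abs(shared_a$se * abs(weights[1]) - shared_b$se),
    adj_r2 = abs(fit_a$adj_r2 - fit_b$adj_r2),
    sbc = abs(fit_a$sbc - fit_b$sbc))
  if (!is.null(interaction_with)) {
    pa <- ca[ca$term == paste0(comp_label, ":E"), ]
    pb <- cb[cb$term == paste0(sources[1], ":E"), ]
    disc <- c(disc,
              interaction_coef = abs(pa$estimate * weights[1] - pb$estimate),
              interaction_se = abs(pa$se * abs(weights[1]) - pb$se))
  }
  structure(list(discrepancies = disc,
                 max_discrepancy = max(disc),
                 pass = unit && max(disc) < tol,
                 unit_weights = unit,
                 note = if (!unit)
                   "non-unit composite weights: intentionally non-equivalent to the all-equal restriction",
                 fit_composite = fit_a,
                 fit_restricted = fit_b,
                 tol = tol),
            class = "cr_equivalence")
}

#' @export
print.cr_equivalence <- function(x, ...) {
  cat("Composite-vs-constraint equivalence check\n")
  print(signif(x$discrepancies, 4))
  cat("max discrepancy:", format(x$max_discrepancy), " tol:", x$tol, "\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  cat(if (x$pass) "EQUIVALENT\n" else "NOT equivalent\n")
  invisible(x)
}
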