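# Nested-model F tests, model ladders, and the three-principles report
# ("do no harm overall", "do no harm in particular", "do some good").

#' Compare nested regression models
#'
#' The F ratio for nested models computed from squared multiple correlations,
#' `F = ((R2_full - R2_restr)/df1) / ((1 - R2_full)/df2)` with
#' `df1 = k_free(full) - k_free(restricted)` and `df2 = n - k_free(full)`,
#' where `k_free` counts free parameters including the intercept.  This is
#' algebraically identical to the SSE-based form
#' `((SSE_r - SSE_f)/df1)/(SSE_f/df2)`.
#'
#' @param full,restricted `cr_fit` objects; `restricted` must have fewer free
#'   parameters.  Nesting is checked structurally when both fits carry their
#'   specs, otherwise trusted with a warning.
#' @param n Sample size (defaults to the full fit's).
#' @return A `cr_comparison`: `delta_r2` (restricted minus full), `f`, `df1`,
#'   `df2`, `p`.
#' @export
compare_nested <- function(full, restricted, n = full$n) {
  stopifnot(inherits(full, "cr_fit"), inherits(restricted, "cr_fit"))
  if (restricted$k_free >= full$k_free)
    stop_validation("restricted model must have fewer free parameters (",
                    restricted$k_free, " vs ", full$k_free, ")")
  if (!identical(full$outcome, restricted$outcome))
    stop_validation("models have different outcomes: ", full$outcome,
                    " vs ", restricted$outcome)
  if (full$n != restricted$n)
    stop_validation("models were fitted on different n: ",
                    full$n, " vs ", restricted$n)
  if (!check_nesting(full, restricted))
    warning("could not verify structural nesting of the models; ",
            "the F test assumes it", call. = FALSE)
  df1 <- full$k_free - restricted$k_free
  df2 <- n - full$k_free
  f <- ((full$r2 - restricted$r2) / df1) / ((1 - full$r2) / df2)
  f <- max(f, 0)
  structure(list(delta_r2 = restricted$r2 - full$r2,
                 f = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE)),
            class = "cr_comparison")
}

# TRUE if nesting is structurally verifiable: identical term sets with the
# restricted model imposing strictly more restrictions, or the restricted
# model's terms a subset of the full model's
check_nesting <- function(full, restricted) {
  if (setequal(full$terms, restricted$terms)) return(TRUE)
  all(restricted$terms %in% full$terms) && restricted$q >= full$q
}

#' @export
print.cr_comparison <- function(x, ...) {
  cat(sprintf("Nested comparison: delta-R2 = %.4f, F(%d, %d) = %.2f, p %s\n",
              x$delta_r2, x$df1, x$df2, x$f, format_p(x$p)))
  invisible(x)
}

format_p <- function(p) if (p < 1e-4) "< .0001" else sprintf("= %.4f", p)

#' Three-principles interrogation report
#'
#' Evaluates a restricted model against the most general model it is nested
#' in:
#' * Principle 1, *do no harm overall*: the nested-model F test must be
#'   non-significant at `alpha`;
#' * Principle 2, *do no harm in particular*: no single restriction's
#'   Lagrange t-test may be significant at `alpha`;
#' * Principle 3, *do some good*: reported evidence only (never gating) --
#'   SE shrinkage on shared terms, adjusted R-squared and BIC improvement.
#'
#' The restricted model is recommended for acceptance iff principles 1 and 2
#' both pass.
#'
#' @inheritParams compare_nested
#' @param alpha Two-sided significance level (default .05).
#' @param adjust Multiple-testing adjustment for the per-restriction tests:
#'   `"none"` (default), `"bonferroni"`, or `"holm"`.
#' @return A `cr_principles` object.
#' @export
principles_report <- function(full, restricted, n = full$n, alpha = 0.05,
                              adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (restricted$k_free == full$k_free &&
      setequal(restricted$terms, full$terms)) {
    # no effective restriction: principles hold vacuously
    cmp <- structure(list(delta_r2 = restricted$r2 - full$r2, f = 0,
                          df1 = 0L, df2 = n - full$k_free, p = 1),
                     class = "cr_comparison")
  } else {
    cmp <- compare_nested(full, restricted, n)
  }
  p1_pass <- cmp$p > alpha
  rt <- restricted$restriction_tests
  if (is.null(rt)) {
    sig <- character(0)
    n_tests <- 0L
  } else {
    pvals <- if (adjust == "none") rt$p else stats::p.adjust(rt$p, adjust)
    sig <- rt$label[pvals <= alpha]
    n_tests <- nrow(rt)
  }
  p2_pass <- length(sig) == 0L
  shared <- intersect(full$terms, restricted$terms)
  se_full <- full$coefficients$se[match(shared, full$coefficients$term)]
  se_restr <- restricted$coefficients$se[match(shared, restricted$coefficients$term)]
  p3 <- list(se_change = data.frame(term = shared, se_full = se_full,
                                    se_restricted = se_restr,
                                    row.names = NULL),
             delta_adj_r2 = restricted$adj_r2 - full$adj_r2,
             delta_sbc = restricted$sbc - full$sbc)
  structure(list(comparison = cmp, alpha = alpha, adjust = adjust,
                 p1 = list(pass = p1_pass, f = cmp$f, df1 = cmp$df1,
                           df2 = cmp$df2, p = cmp$p),
                 p2 = list(pass = p2_pass, n_tests = n_tests,
                           significant = sig),
                 p3 = p3,
                 recommendation = if (p1_pass && p2_pass) "accept restricted"
                                  else "reject restricted"),
            class = "cr_principles")
}

#' @export
print.cr_principles <- function(x, ...) {
  cat("Three-principles interrogation (alpha =", x$alpha, ")\n")
  cat(sprintf("  1. Do no harm overall:     %s  F(%d, %d) = %.2f, p %s\n",
              if (x$p1$pass) "PASS" else "FAIL",
              x$p1$df1, x$p1$df2, x$p1$f, format_p(x$p1$p)))
  cat(sprintf("  2. Do no harm in particular: %s  %d of %d restriction tests significant%s\n",
              if (x$p2$pass) "PASS" else "FAIL",
              length(x$p2$significant), x$p2$n_tests,
              if (length(x$p2$significant))
                paste0(" (", paste(x$p2$significant, collapse = "; "), ")")
              else ""))
  cat(sprintf("  3. Do some good (advisory):  delta adj-R2 = %+.4f, delta BIC = %+.2f\n",
              x$p3$delta_adj_r2, x$p3$delta_sbc))
  cat("  Recommendation:", x$recommendation, "\n")
  invisible(x)
}

#' Fit an ordered ladder of models and compare each to a baseline
#'
#' @param m Data input accepted by [fit_ols] (summary moments, centered
#'   moments, or data frame).
#' @param models Named list; each element is a list with components `spec`
#'   (a [model_spec]) and optionally `restrictions` (a [restriction_set] or
#'   character vector).
#' @param baseline Label of the most general model (default: the model with
#'   the most free parameters).
#' @param alpha Significance level for the principle verdicts.
#' @return A `cr_ladder`: per-model fits, comparisons against the baseline,
#'   principle reports, and a summary table ranked as given with the
#'   SBC-optimal model flagged.
#' @export
run_ladder <- function(m, models, baseline = NULL, alpha = 0.05) {
  if (length(models) < 2)
    stop_validation("a ladder needs >= 2 models (baseline required)")
  labels <- names(models)
  if (is.null(labels) || any(!nzchar(labels)))
    stop_validation("models must be a named list")
  if (anyDuplicated(labels))
    stop_validation("duplicate model labels: ",
                    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  fits <- lapply(models, function(mod) {
    fit_ols(m, mod$spec, mod$restrictions)
  })
  names(fits) <- labels
  if (is.null(baseline))
    baseline <- labels[which.max(vapply(fits, `[[`, 0L, "k_free"))]
  if (!baseline %in% labels)
    stop_validation("baseline '", baseline, "' is not a model label")
  base_fit <- fits[[baseline]]
  comparisons <- list()
  principles <- list()
  for (lab in labels) {
    if (lab == baseline) next
    if (fits[[lab]]$k_free < base_fit$k_free) {
      comparisons[[lab]] <- compare_nested(base_fit, fits[[lab]])
      principles[[lab]] <- principles_report(base_fit, fits[[lab]],
                                             alpha = alpha)
    }
  }
  tab <- data.frame(
    model = labels,
    k_free = vapply(fits, `[[`, 0L, "k_free"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    adj_r2 = vapply(fits, `[[`, 0, "adj_r2"),
    sbc = vapply(fits, `[[`, 0, "sbc"),
    f_vs_baseline = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
    p_vs_baseline = NA_real_,
    row.names = NULL)
  for (lab in names(comparisons)) {
    i <- match(lab, tab$model)
    tab$f_vs_baseline[i] <- comparisons[[lab]]$f
    tab$df1[i] <- comparisons[[lab]]$df1
    tab$df2[i] <- comparisons[[lab]]$df2
    tab$p_vs_baseline[i] <- comparisons[[lab]]$p
  }
  structure(list(table = tab, fits = fits, comparisons = comparisons,
                 principles = principles, baseline = baseline,
                 sbc_optimal = tab$model[which.min(tab$sbc)]),
            class = "cr_ladder")
}

#' @export
print.cr_ladder <- function(x, ...) {
  cat("Model ladder (baseline:", x$baseline, ")\n")
  tab <- x$table
  tab$r2 <- sprintf("%.4f", tab$r2)
  tab$adj_r2 <- sprintf("%.4f", tab$adj_r2)
  tab$sbc <- sprintf("%.2f", tab$sbc)
  tab$f_vs_baseline <- ifelse(is.na(tab$f_vs_baseline), "",
                              sprintf("%.2f", tab$f_vs_baseline))
  tab$p_vs_baseline <- vapply(x$table$p_vs_baseline, function(p)
    if (is.na(p)) "" else sub("^= ", "", format_p(p)), "")
  print(tab, row.names = FALSE)
  cat("SBC-optimal model:", x$sbc_optimal, "\n")
  for (lab in names(x$principles)) {
    cat("\n--", lab, "vs", x$baseline, "--\n")
    print(x$principles[[lab]])
  }
  invisible(x)
}
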