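# Ordinary and linearly restricted least squares fitted from sufficient
# statistics, so that published correlation tables and raw data tables are
# interchangeable inputs.
#
# All fitting funnels through fit_core(), which works in the augmented
# normal-equation space M = X'X (intercept included).  Restricted estimates
# use the bordered normal equations:
#   beta_r = beta_hat - M^-1 L'(L M^-1 L')^-1 (L beta_hat - c)
#   SSE_r  = SSE + (L beta_hat - c)'(L M^-1 L')^-1 (L beta_hat - c)
#   lambda = (L M^-1 L')^-1 (L beta_hat - c),  Var(lambda) = s2_r (L M^-1 L')^-1
# with s2_r = SSE_r / (n - k_free), k_free = p + 1 - q.  The per-restriction
# t-ratio lambda/SE(lambda) on n - k_free df is the single-constraint
# "do no harm in particular" test.

#' Fit a model by ordinary least squares
#'
#' Accepts three kinds of input interchangeably: a [summary_moments] object
#' (models with plain-column and composite terms only), a raw data frame, or
#' a `centered_moments` block whose predictors match the model's term labels.
#' Summary-path and raw-path fits agree to numerical precision whenever the
#' raw sample moments equal the summary moments.
#'
#' @param m Input data: `summary_moments`, `centered_moments`, or data frame.
#' @param spec A [model_spec].
#' @param restrictions Optional [restriction_set] or character vector of
#'   restriction expressions (see [parse_restrictions]).
#' @param na_action Passed to [moments_from_raw] on the raw-data path.
#' @return A `cr_fit` object: coefficient table (estimate, SE, t, p, free or
#'   implied-by-restriction), SSE, error df, R-squared, adjusted R-squared,
#'   Schwarz BIC, overall F, and per-restriction Lagrange tests.
#' @export
fit_ols <- function(m, spec, restrictions = NULL, na_action = "fail") {
  if (is.character(restrictions))
    restrictions <- parse_restrictions(restrictions, spec)
  if (!is.null(restrictions) && !inherits(restrictions, "restriction_set"))
    stop_validation("restrictions must be a restriction_set or character vector")
  if (!is.null(restrictions) &&
      !identical(colnames(restrictions$L), spec$labels))
    restrictions <- align_restrictions(restrictions, spec$labels)
  dm <- if (inherits(m, "centered_moments")) {
    if (!identical(m$predictors, spec$labels))
      stop_validation("centered_moments predictors do not match model terms")
    m
  } else if (inherits(m, "summary_moments")) {
    design_moments(m, spec)
  } else if (is.data.frame(m)) {
    frame <- prepare_model_frame(m, spec, na_action = na_action)
    mm <- moments_from_raw(frame, names(frame))
    center_moments(mm, spec$outcome, spec$labels)
  } else {
    stop_validation("unsupported input of class ", paste(class(m), collapse = "/"))
  }
  fit_core(dm, restrictions, spec = spec)
}

#' @rdname fit_ols
#' @export
fit_restricted <- function(m, spec, restrictions, na_action = "fail") {
  if (is.null(restrictions))
    stop_validation("fit_restricted requires restrictions; use fit_ols otherwise")
  fit_ols(m, spec, restrictions, na_action = na_action)
}

#' @rdname fit_ols
#' @param data A raw data frame (one row per participant).
#' @export
fit_from_raw <- function(data, spec, restrictions = NULL, na_action = "fail") {
  if (!is.data.frame(data)) stop_validation("data must be a data frame")
  fit_ols(data, spec, restrictions, na_action = na_action)
}

# pad/reorder a restriction matrix whose columns name a subset of the terms
align_restrictions <- function(restr, labels) {
  unknown <- setdiff(colnames(restr$L), labels)
  if (length(unknown))
    stop_validation("restriction(s) reference undeclared term(s): ",
                    paste(unknown, collapse = ", "))
  L <- matrix(0, restr$q, length(labels), dimnames = list(NULL, labels))
  L[, colnames(restr$L)] <- restr$L
  restriction_set(L, restr$c, restr$labels, terms = labels)
}

# Map a model's terms onto summary moments.  Plain columns and composites
# are linear in the source variables, so the term-level covariance block is
# A S A' for a weight matrix A; centering flags zero the term mean without
# touching covariances.  Products are nonlinear and need raw data.
design_moments <- function(m, spec) {
  for (tm in spec$terms)
    if (tm$kind == "product" && !(tm$label %in% m$names))
      stop_validation("product term '", tm$label,
                      "' cannot be formed from summary moments; ",
                      "fit from raw data, or supply moments that include it")
  p <- length(spec$terms)
  vars <- m$names
  A <- matrix(0, p, length(vars), dimnames = list(spec$labels, vars))
  centered <- logical(p)
  for (i in seq_len(p)) {
    tm <- spec$terms[[i]]
    src <- if (tm$kind == "product") tm$label else tm$cols
    unknown <- setdiff(src, vars)
    if (length(unknown))
      stop_validation("term '", tm$label, "' references unknown variable(s): ",
                      paste(unknown, collapse = ", "),
                      "; available: ", paste(vars, collapse = ", "))
    w <- if (tm$kind == "composite") tm$weights else 1
    A[i, src] <- w
    centered[i] <- tm$kind == "col" && isTRUE(tm$center)
  }
  if (!(spec$outcome %in% vars))
    stop_validation("outcome '", spec$outcome, "' not among variables: ",
                    paste(vars, collapse = ", "))
  S <- moments_cov(m)
  means <- drop(A %*% m$means)
  means[centered] <- 0
  centered_moments(outcome = spec$outcome, predictors = spec$labels, n = m$n,
                   mean_y = m$means[[spec$outcome]],
                   means_x = means,
                   sy2 = S[spec$outcome, spec$outcome],
                   Cxx = A %*% S %*% t(A),
                   Cxy = drop(A %*% S[, spec$outcome]))
}

#' Build the model frame for a specification from raw data
#'
#' Materializes each term as a numeric column: centering (analysis-sample
#' mean, after any listwise deletion), products of centered factors, and
#' weighted composites.  The returned frame holds the outcome followed by
#' one column per term, named by term label.
#'
#' @inheritParams fit_ols
#' @return A data frame; centering constants are recorded in
#'   `attr(, "centering")`.
#' @export
prepare_model_frame <- function(data, spec, na_action = "fail") {
  needed <- unique(c(spec$outcome, unlist(lapply(spec$terms, `[[`, "cols"))))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop_validation("unknown column(s): ", paste(missing_cols, collapse = ", "),
                    "; available: ", paste(names(data), collapse = ", "))
  non_num <- needed[!vapply(data[needed], is.numeric, logical(1))]
  if (length(non_num))
    stop_validation("non-numeric modeled column(s): ",
                    paste(non_num, collapse = ", "))
  dat <- data[needed]
  if (anyNA(dat)) {
    if (identical(na_action, "fail"))
      stop_validation("missing values in modeled columns; use na_action = 'listwise'")
    keep <- stats::complete.cases(dat)
    message("listwise deletion: dropped ", sum(!keep), " of ", nrow(dat), " rows")
    dat <- dat[keep, , drop = FALSE]
  }
  centering <- numeric()
  ctr <- function(col) {
    mu <- mean(dat[[col]])
    centering[[col]] <<- mu
    dat[[col]] - mu
  }
  out <- data.frame(row.names = seq_len(nrow(dat)))
  out[[spec$outcome]] <- dat[[spec$outcome]]
  for (tm in spec$terms) {
    col <- switch(tm$kind,
      col = if (isTRUE(tm$center)) ctr(tm$cols) else dat[[tm$cols]],
      product = {
        a <- if (isTRUE(tm$center[1])) ctr(tm$cols[1]) else dat[[tm$cols[1]]]
        b <- if (isTRUE(tm$center[2])) ctr(tm$cols[2]) else dat[[tm$cols[2]]]
        a * b
      },
      composite = as.matrix(dat[tm$cols]) %*% tm$weights)
    out[[tm$label]] <- as.numeric(col)
  }
  if (nrow(out) < length(spec$terms) + 2)
    stop_validation("need at least ", length(spec$terms) + 2,
                    " complete rows for ", length(spec$terms),
                    " predictors, got ", nrow(out))
  attr(out, "centering") <- centering
  out
}

fit_core <- function(dm, restr = NULL, spec = NULL) {
  p <- length(dm$predictors)
  n <- dm$n
  labels <- dm$predictors
  q <- if (is.null(restr)) 0L else restr$q
  if (q > p)
    stop_validation("more restrictions (", q, ") than slope terms (", p, ")")
  if (n - (p + 1L - q) < 1L)
    stop_validation("no error degrees of freedom: n = ", n,
                    ", free parameters = ", p + 1L - q)
  mx <- dm$means_x
  # augmented cross-product matrix M = X'X, first row/col = intercept
  if (p > 0) {
    check_invertible(dm$Cxx, labels)
    M <- rbind(c(n, n * mx),
               cbind(n * mx, (n - 1) * dm$Cxx + n * outer(mx, mx)))
    Xty <- c(n * dm$mean_y, (n - 1) * dm$Cxy + n * mx * dm$mean_y)
  } else {
    M <- matrix(n, 1, 1)
    Xty <- n * dm$mean_y
  }
  dimnames(M) <- list(c("(Intercept)", labels), c("(Intercept)", labels))
  yty <- (n - 1) * dm$sy2 + n * dm$mean_y^2
  R <- tryCatch(chol(M), error = function(e)
    stop_numeric("normal equations not positive definite: ", conditionMessage(e)))
  Minv <- chol2inv(R)
  beta_hat <- drop(Minv %*% Xty)
  sst <- (n - 1) * dm$sy2
  sse <- max(yty - sum(beta_hat * Xty), 0)

  restriction_tests <- NULL
  if (q > 0) {
    La <- cbind(0, restr$L)              # intercept column is never restricted
    A <- La %*% Minv %*% t(La)
    Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
      stop_numeric("restrictions are numerically degenerate: ",
                   conditionMessage(e)))
    d <- drop(La %*% beta_hat) - restr$c
    lambda <- drop(Ainv %*% d)
    beta <- beta_hat - drop(Minv %*% t(La) %*% lambda)
    sse_fit <- sse + drop(t(d) %*% Ainv %*% d)
    k_free <- p + 1L - q
    s2 <- sse_fit / (n - k_free)
    V <- s2 * (Minv - Minv %*% t(La) %*% Ainv %*% La %*% Minv)
    se_lambda <- sqrt(pmax(diag(s2 * Ainv), 0))
    t_lambda <- lambda / se_lambda
    restriction_tests <- data.frame(
      label = restr$labels,
      estimate = lambda,
      se = se_lambda,
      t = t_lambda,
      df = n - k_free,
      p = 2 * stats::pt(abs(t_lambda), n - k_free, lower.tail = FALSE),
      row.names = NULL)
    free <- c(TRUE, colSums(restr$L != 0) == 0)
  } else {
    beta <- beta_hat
    sse_fit <- sse
    k_free <- p + 1L
    s2 <- sse_fit / (n - k_free)
    V <- s2 * Minv
    free <- rep(TRUE, p + 1L)
  }
  se <- sqrt(pmax(diag(V), 0))
  tval <- ifelse(se > 0, beta / se, NA_real_)
  df_error <- n - k_free
  coef_tab <- data.frame(
    term = c("(Intercept)", labels),
    estimate = unname(beta),
    se = unname(se),
    t = unname(tval),
    p = 2 * stats::pt(abs(tval), df_error, lower.tail = FALSE),
    free = free,
    row.names = NULL)
  r2 <- if (sst > 0) 1 - sse_fit / sst else NA_real_
  df_model <- k_free - 1L
  fstat <- if (df_model >= 1L && is.finite(r2) && r2 < 1)
    (r2 / df_model) / ((1 - r2) / df_error) else NA_real_
  structure(list(
    coefficients = coef_tab,
    restriction_tests = restriction_tests,
    outcome = dm$outcome,
    terms = labels,
    n = n,
    k_free = k_free,
    q = q,
    sse = sse_fit,
    sst = sst,
    sigma2 = s2,
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k_free),
    sbc = n * log(sse_fit / n) + k_free * log(n),
    fstatistic = c(value = fstat, df1 = df_model, df2 = df_error),
    vcov = V,
    spec = spec,
    restrictions = restr), class = "cr_fit")
}

# singularity diagnostics: fail above condition number 1e12, naming a
# linearly dependent column subset via pivoted QR
check_invertible <- function(Cxx, labels) {
  if (length(labels) == 1L) {
    if (Cxx[1, 1] <= 0) stop_numeric("predictor '", labels, "' has zero variance")
    return(invisible())
  }
  qrC <- qr(Cxx)
  if (qrC$rank < length(labels)) {
    dep <- labels[qrC$pivot[(qrC$rank + 1L):length(labels)]]
    stop_numeric("singular predictor cross-product matrix; column(s) ",
                 paste(dep, collapse = ", "),
                 " are linearly dependent on the others")
  }
  kap <- kappa(Cxx, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stop_numeric("predictor cross-product matrix is ill-conditioned ",
                 "(condition number ", signif(kap, 3), " > 1e12)")
  invisible()
}

#' Fit and parsimony indices
#'
#' Adjusted R-squared, `1 - (1 - R^2)(n-1)/(n-k)`, and the Schwarz Bayesian
#' criterion, `n*log(SSE/n) + k*log(n)`, where `k` counts free parameters
#' including the intercept.  Both are already stored on a `cr_fit`; this
#' recomputes them for an arbitrary `n`.
#'
#' @param fit A `cr_fit`.
#' @param n Sample size (defaults to the fit's own).
#' @return A list with elements `adj_r2` and `sbc`.
#' @export
fit_indices <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "cr_fit"))
  k <- fit$k_free
  list(adj_r2 = 1 - (1 - fit$r2) * (n - 1) / (n - k),
       sbc = n * log(fit$sse / n) + k * log(n))
}

#' @export
print.cr_fit <- function(x, digits = 2, ...) {
  cat("Least-squares fit: ", x$outcome, " ~ ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "\n", sep = "")
  if (x$q > 0) cat("  with", x$q, "linear restriction(s)\n")
  tab <- x$coefficients
  fmt <- data.frame(
    Variable = tab$term,
    df = ifelse(tab$free, 1L, 1L),
    `B (SE)` = sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                       tab$estimate, tab$se),
    t = sprintf("%.2f", tab$t),
    check.names = FALSE)
  print(fmt, row.names = FALSE, right = FALSE)
  if (!is.null(x$restriction_tests)) {
    rt <- x$restriction_tests
    fmt_r <- data.frame(
      Restriction = rt$label,
      df = -1L,
      `B (SE)` = sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                         rt$estimate, rt$se),
      t = sprintf("%.2f", rt$t),
      check.names = FALSE)
    print(fmt_r, row.names = FALSE, right = FALSE)
  }
  cat(sprintf("R2 = %.4f   adj-R2 = %.4f   F(%d, %d) = %.2f   BIC = %.2f\n",
              x$r2, x$adj_r2, x$fstatistic["df1"], x$fstatistic["df2"],
              x$fstatistic["value"], x$sbc))
  invisible(x)
}

#' Serializable report of a fit
#'
#' @param fit A `cr_fit`.
#' @return A plain list (coefficients, restriction tests, fit statistics)
#'   suitable for `jsonlite::toJSON`.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "cr_fit"))
  list(outcome = fit$outcome,
       terms = fit$terms,
       n = fit$n,
       k_free = fit$k_free,
       coefficients = fit$coefficients,
       restriction_tests = fit$restriction_tests,
       sse = fit$sse,
       r2 = fit$r2,
       adj_r2 = fit$adj_r2,
       sbc = fit$sbc,
       f = unname(fit$fstatistic["value"]),
       df1 = unname(fit$fstatistic["df1"]),
       df2 = unname(fit$fstatistic["df2"]))
}
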