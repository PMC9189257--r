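# Summary-moment containers: the sufficient statistics for every regression
# in the package (variable names, N, means, SDs, correlation matrix).

#' Construct a summary-moments object
#'
#' A `summary_moments` object holds the regression-sufficient statistics of a
#' dataset: variable names, sample size, per-variable means and standard
#' deviations, and the Pearson correlation matrix.  Every model in the package
#' can be fitted from such an object alone, so published correlation tables
#' are first-class inputs.
#'
#' @param names Character vector of variable labels (order is preserved).
#' @param n Integer sample size (>= 3).
#' @param means Numeric vector of means, one per variable.
#' @param sds Numeric vector of standard deviations (N-1 denominator), all > 0.
#' @param corr Square correlation matrix; symmetric with unit diagonal.
#'   Asymmetry beyond 1e-10 is an error.  A smallest eigenvalue in
#'   `[-1e-8, 0)` triggers a warning (rounded published correlations are often
#'   slightly indefinite); below -1e-8 is an error.
#' @return An object of class `summary_moments`.
#' @export
summary_moments <- function(names, n, means, sds, corr) {
  names <- as.character(names)
  p <- length(names)
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop_validation("n must be an integer >= 3, got ", n)
  if (anyDuplicated(names))
    stop_validation("duplicate variable names: ",
                    paste(unique(names[duplicated(names)]), collapse = ", "))
  if (length(means) != p || length(sds) != p)
    stop_validation("names, means and sds must have equal length (",
                    p, ", ", length(means), ", ", length(sds), ")")
  if (any(!is.finite(means)) || any(!is.finite(sds)))
    stop_validation("means and sds must be finite")
  if (any(sds <= 0))
    stop_validation("all SDs must be > 0; offending variable(s): ",
                    paste(names[sds <= 0], collapse = ", "))
  corr <- as.matrix(corr)
  if (nrow(corr) != p || ncol(corr) != p)
    stop_validation("corr must be ", p, " x ", p, ", got ",
                    nrow(corr), " x ", ncol(corr))
  asym <- abs(corr - t(corr))
  if (max(asym) > 1e-10) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_validation("correlation matrix is asymmetric at cell (",
                    names[ij[1]], ", ", names[ij[2]], "): ",
                    corr[ij[1], ij[2]], " vs ", corr[ij[2], ij[1]])
  }
  corr <- (corr + t(corr)) / 2
  if (max(abs(diag(corr) - 1)) > 1e-10)
    stop_validation("correlation matrix diagonal must be 1")
  if (any(corr < -1 - 1e-10 | corr > 1 + 1e-10))
    stop_validation("off-diagonal correlations must lie in [-1, 1]")
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop_validation("correlation matrix is not positive semidefinite ",
                    "(smallest eigenvalue ", signif(ev, 4), ")")
  if (ev < 0)
    warning("correlation matrix is marginally indefinite (smallest eigenvalue ",
            signif(ev, 4), "); typical for rounded published tables",
            call. = FALSE)
  dimnames(corr) <- list(names, names)
  structure(list(names = names, n = n,
                 means = stats::setNames(as.numeric(means), names),
                 sds = stats::setNames(as.numeric(sds), names),
                 corr = corr),
            class = "summary_moments")
}

#' @export
print.summary_moments <- function(x, digits = 3, ...) {
  cat("Summary moments: ", length(x$names), " variables, N = ", x$n, "\n",
      sep = "")
  tab <- rbind(Mean = x$means, SD = x$sds)
  print(round(tab, digits))
  invisible(x)
}

#' Covariance matrix implied by summary moments
#'
#' @param m A `summary_moments` object.
#' @return The covariance matrix `diag(sds) %*% corr %*% diag(sds)`.
#' @export
moments_cov <- function(m) {
  stopifnot(inherits(m, "summary_moments"))
  S <- diag(m$sds) %*% m$corr %*% diag(m$sds)
  dimnames(S) <- list(m$names, m$names)
  S
}

#' Read a summary-moment bundle
#'
#' A bundle is a pair of CSV files sharing a prefix: `<prefix>.corr.csv`
#' (row labels in the first column, a square -- or lower-triangular, which is
#' mirrored -- correlation matrix) and `<prefix>.meta.csv` (columns
#' `variable`, `mean`, `sd`, plus one row with `variable == "n"` whose `mean`
#' field carries the sample size).
#'
#' @param source Path prefix of the bundle, or the `.corr.csv` path itself.
#' @param n Optional integer sample size, overriding the meta file.
#' @return A validated [summary_moments] object; variable order as given.
#' @export
load_summary <- function(source, n = NULL) {
  prefix <- sub("\\.corr\\.csv$", "", source)
  corr_path <- paste0(prefix, ".corr.csv")
  meta_path <- paste0(prefix, ".meta.csv")
  if (!file.exists(corr_path))
    stop_validation("correlation file not found: ", corr_path)
  cr <- utils::read.csv(corr_path, check.names = FALSE)
  nms <- as.character(cr[[1]])
  C <- as.matrix(cr[, -1, drop = FALSE])
  mode(C) <- "numeric"
  if (nrow(C) != ncol(C))
    stop_validation("correlation block is not square: ",
                    nrow(C), " x ", ncol(C))
  # accept lower-triangle input (NAs above the diagonal) and mirror it
  if (anyNA(C)) {
    up <- upper.tri(C)
    if (all(is.na(C[up])) && !anyNA(C[!up])) {
      C[up] <- t(C)[up]
    } else {
      stop_validation("NA cells in correlation matrix outside the upper triangle")
    }
  }
  if (!file.exists(meta_path)) {
    stop_validation("meta file with means/SDs not found: ", meta_path)
  }
  meta <- utils::read.csv(meta_path, check.names = FALSE)
  need <- c("variable", "mean", "sd")
  if (!all(need %in% names(meta)))
    stop_validation("meta file must have columns variable, mean, sd")
  n_row <- meta$variable == "n"
  if (is.null(n)) {
    if (!any(n_row)) stop_validation("no 'n' record in meta file and no n given")
    n <- as.integer(meta$mean[n_row][1])
  }
  meta <- meta[!n_row, , drop = FALSE]
  idx <- match(nms, meta$variable)
  if (anyNA(idx))
    stop_validation("meta file is missing variable(s): ",
                    paste(nms[is.na(idx)], collapse = ", "))
  summary_moments(nms, n, meta$mean[idx], meta$sd[idx], C)
}

#' Write a summary-moment bundle
#'
#' Inverse of [load_summary]: writes `<prefix>.corr.csv` (full square matrix)
#' and `<prefix>.meta.csv`.
#'
#' @param m A `summary_moments` object.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_summary <- function(m, prefix) {
  stopifnot(inherits(m, "summary_moments"))
  cr <- data.frame(variable = m$names, m$corr, check.names = FALSE)
  utils::write.csv(cr, paste0(prefix, ".corr.csv"), row.names = FALSE)
  meta <- data.frame(variable = c(m$names, "n"),
                     mean = c(unname(m$means), m$n),
                     sd = c(unname(m$sds), NA))
  utils::write.csv(meta, paste0(prefix, ".meta.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Compute summary moments from a raw data table
#'
#' Means, standard deviations (N-1 denominator) and Pearson correlations of
#' the selected columns.  Missing values are disallowed in modeled columns;
#' set `na_action = "listwise"` to drop incomplete rows with a message.
#'
#' @param data A data frame of numeric columns.
#' @param variables Column names to summarize (default: all columns).
#' @param na_action `"fail"` (default) or `"listwise"`.
#' @return A [summary_moments] object.
#' @export
moments_from_raw <- function(data, variables = names(data),
                             na_action = c("fail", "listwise")) {
  na_action <- match.arg(na_action)
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols))
    stop_validation("unknown column(s): ", paste(missing_cols, collapse = ", "),
                    "; available: ", paste(names(data), collapse = ", "))
  X <- data[variables]
  non_num <- !vapply(X, is.numeric, logical(1))
  if (any(non_num))
    stop_validation("non-numeric modeled column(s): ",
                    paste(variables[non_num], collapse = ", "))
  X <- as.matrix(X)
  if (anyNA(X)) {
    if (na_action == "fail")
      stop_validation("missing values in modeled columns; use na_action = 'listwise'")
    keep <- stats::complete.cases(X)
    message("listwise deletion: dropped ", sum(!keep), " of ", nrow(X), " rows")
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X)
  if (n < 3L) stop_validation("need at least 3 complete rows, got ", n)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_validation("constant column(s): ",
                    paste(variables[sds == 0], collapse = ", "))
  summary_moments(variables, n, colMeans(X), sds, stats::cor(X))
}

#' Restrict summary moments to centered sufficient statistics
#'
#' Extracts the block of moments needed to fit `outcome ~ predictors`:
#' the predictor covariance matrix `C_xx` and predictor-outcome covariance
#' vector `C_xy` (both on the N-1 denominator), the outcome variance, and
#' all means.
#'
#' @param m A [summary_moments] object.
#' @param outcome Outcome variable name.
#' @param predictors Character vector of predictor names (order preserved).
#' @return An object of class `centered_moments`.
#' @export
center_moments <- function(m, outcome, predictors) {
  stopifnot(inherits(m, "summary_moments"))
  vars <- c(outcome, predictors)
  unknown <- setdiff(vars, m$names)
  if (length(unknown))
    stop_validation("unknown variable(s): ", paste(unknown, collapse = ", "),
                    "; available: ", paste(m$names, collapse = ", "))
  if (anyDuplicated(vars))
    stop_validation("outcome and predictors must be distinct")
  S <- moments_cov(m)
  centered_moments(outcome = outcome, predictors = predictors, n = m$n,
                   mean_y = m$means[[outcome]],
                   means_x = m$means[predictors],
                   sy2 = S[outcome, outcome],
                   Cxx = S[predictors, predictors, drop = FALSE],
                   Cxy = S[predictors, outcome])
}

# Internal constructor for the centered sufficient-statistic block.
centered_moments <- function(outcome, predictors, n, mean_y, means_x, sy2,
                             Cxx, Cxy) {
  structure(list(outcome = outcome, predictors = predictors, n = as.integer(n),
                 mean_y = unname(mean_y),
                 means_x = stats::setNames(as.numeric(means_x), predictors),
                 sy2 = unname(sy2),
                 Cxx = Cxx, Cxy = stats::setNames(as.numeric(Cxy), predictors)),
            class = "centered_moments")
}

#' Packaged summary-moment fixtures
#'
#' Published correlation tables shipped with the package:
#' * `"sameroff_table2"`: child WPPSI Verbal IQ and 10 dichotomous
#'   environmental risk indicators, N = 215.
#' * `"masarik_table5"`: target and parent hostility with gene total,
#'   dominant and recessive indices, N = 281.
#' * `"masarik_table6"`: dominant and recessive codes for five SNPs,
#'   N = 281.
#'
#' @param name Fixture name.
#' @return A [summary_moments] object.
#' @export
cr_fixture <- function(name = c("sameroff_table2", "masarik_table5",
                                "masarik_table6")) {
  name <- match.arg(name)
  prefix <- system.file("extdata", name, package = "crindex")
  if (prefix == "")
    prefix <- file.path(system.file("extdata", package = "crindex"), name)
  load_summary(prefix)
}

# condition helpers: validation errors carry their own class so callers
# (and the command-line front-end) can distinguish bad input from numerics
stop_validation <- function(...) {
  stop(structure(class = c("crindex_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("crindex_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
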