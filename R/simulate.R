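# Seed-deterministic synthetic data: exact moment matching, a latent-
# threshold generator for correlated dichotomous risk indicators, and a
# Hardy-Weinberg G x E generator with a strong-differential-susceptibility
# default.  Every generator uses one explicitly seeded pseudo-random stream
# and restores the caller's random state on exit.

with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# symmetric PSD square root of a correlation matrix; tolerates slightly
# negative eigenvalues from rounded published tables
psd_factor <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -tol)
    stop_validation("matrix is not positive semidefinite (smallest eigenvalue ",
                    signif(min(e$values), 4),
                    "); consider a nearest-PSD repair before sampling")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Draw a sample whose moments match a target exactly
#'
#' Constructs an `n x p` data table whose sample means, standard deviations
#' (N-1 denominator) and Pearson correlations equal the target summary
#' moments to numerical precision, not just in expectation: a seeded random
#' matrix is column-centered, its columns orthonormalized, scaled by
#' `sqrt(n-1)`, rotated by a square root of the target correlation matrix,
#' rescaled by the target SDs and shifted to the target means.  Different
#' seeds give different tables with identical moments.
#'
#' @param m A [summary_moments] target.
#' @param n Number of rows (default `m$n`); must exceed the number of
#'   variables + 1.
#' @param seed Integer seed.
#' @return A data frame with `m$names` as columns.
#' @export
exact_moment_sample <- function(m, n = m$n, seed = 1) {
  stopifnot(inherits(m, "summary_moments"))
  p <- length(m$names)
  if (n <= p + 1)
    stop_validation("n must exceed the number of variables + 1 (", p + 1, ")")
  F <- psd_factor(m$corr)
  with_local_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(Z))                      # orthonormal, orthogonal to 1
    X <- sqrt(n - 1) * Q %*% F
    X <- sweep(X, 2, m$sds, `*`)
    X <- sweep(X, 2, m$means, `+`)
    out <- as.data.frame(X)
    names(out) <- m$names
    out
  })
}

#' Simulate a gene-by-environment dataset
#'
#' SNP allele counts are drawn independently as Binomial(2, freq) --
#' Hardy-Weinberg equilibrium with no linkage or gene-environment
#' correlation.  A 0/1 covariate is Bernoulli, the environment is normal,
#' and the outcome follows
#' `y = b0 + b_cov*cov + b_env*Ec + b_gene*G + b_gxe*G*Ec + e`,
#' with `Ec` the environment centered at its *true* mean and `G` the gene
#' total (sum of allele counts).
#'
#' The defaults emulate a strong-differential-susceptibility structure at
#' the scale of the hostility study: n = 281, five SNPs with allele
#' frequencies implied by the published gene-index means, zero E and G main
#' effects and a G x E slope of 0.07 on the gene-total scale.
#'
#' @param n Sample size (>= 30).
#' @param allele_freq Per-SNP plasticity-allele probabilities in (0, 1).
#' @param snp_names SNP column names.
#' @param cov_prevalence P(covariate = 1).
#' @param env_mean,env_sd Environment mean and SD (> 0).
#' @param b0,b_cov,b_env,b_gene,b_gxe Generating coefficients (gene-total
#'   scale).
#' @param resid_sd Residual SD (> 0).
#' @param seed Integer seed.
#' @return A data frame with columns `y`, `Female`, `E`, the SNP allele
#'   counts, and `gene_total`.  The true environment mean used for
#'   centering is stored in `attr(, "env_center")`.
#' @export
simulate_gxe <- function(n = 281,
                         allele_freq = c(ANKK1 = 0.19, DRD4 = 0.19,
                                         DAT = 0.74, HTT5 = 0.49,
                                         COMT = 0.58),
                         snp_names = names(allele_freq),
                         cov_prevalence = 0.5,
                         env_mean = 3.63, env_sd = 1.43,
                         b0 = 2.96, b_cov = 0.95, b_env = 0,
                         b_gene = 0, b_gxe = 0.07,
                         resid_sd = 1.5, seed = 1) {
  if (n < 30) stop_validation("n must be >= 30")
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop_validation("allele frequencies must lie in (0, 1)")
  if (env_sd <= 0 || resid_sd <= 0)
    stop_validation("env_sd and resid_sd must be > 0")
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_along(allele_freq))
  with_local_seed(seed, {
    G <- vapply(allele_freq, function(f) stats::rbinom(n, 2, f),
                numeric(n))
    colnames(G) <- snp_names
    total <- rowSums(G)
    female <- stats::rbinom(n, 1, cov_prevalence)
    env <- stats::rnorm(n, env_mean, env_sd)
    ec <- env - env_mean
    y <- b0 + b_cov * female + b_env * ec + b_gene * total +
      b_gxe * total * ec + stats::rnorm(n, 0, resid_sd)
    out <- data.frame(y = y, Female = female, E = env, G,
                      gene_total = total, check.names = FALSE)
    attr(out, "env_center") <- env_mean
    out
  })
}

#' Simulate correlated dichotomous risk indicators and an outcome
#'
#' Indicators follow a latent-threshold model: a multivariate normal latent
#' vector with the given correlation matrix is dichotomized so that
#' indicator j equals 1 with probability `prevalence[j]` (the latent score
#' exceeds its upper `prevalence[j]` quantile).  A positive-manifold latent
#' correlation reproduces the mutually positive indicator correlations
#' typical of environmental-risk batteries.  The outcome is a weighted sum
#' of the indicators plus normal noise.
#'
#' Defaults emulate the 10-indicator verbal-IQ study: prevalences equal to
#' the published indicator means, an exchangeable latent correlation of .45,
#' weights of -8.6 for the first four ("classic") indicators and -1.43 for
#' the remaining six, intercept 114.9 and residual SD 12.7 (giving an
#' outcome SD near 18 and R-squared near .5 at those weights).
#'
#' @param n Sample size.
#' @param prevalence Per-indicator P(indicator = 1), in (0, 1).
#' @param latent_corr Latent correlation matrix (default exchangeable .45).
#' @param weights Outcome units per risk, one per indicator.
#' @param intercept Outcome intercept.
#' @param resid_sd Residual SD (> 0).
#' @param names Indicator column names.
#' @param seed Integer seed.
#' @return A data frame with the outcome `y` and one 0/1 column per
#'   indicator.
#' @export
simulate_risk_indicators <- function(n = 215,
                                     prevalence = c(.20, .40, .39, .25, .40,
                                                    .18, .25, .25, .25, .25),
                                     latent_corr = NULL,
                                     weights = c(rep(-8.6, 4), rep(-1.43, 6)),
                                     intercept = 114.9, resid_sd = 12.7,
                                     names = NULL, seed = 1) {
  p <- length(prevalence)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop_validation("prevalences must lie in (0, 1)")
  if (length(weights) != p)
    stop_validation("need one weight per indicator (", p, ")")
  if (resid_sd <= 0) stop_validation("resid_sd must be > 0")
  if (is.null(latent_corr)) {
    latent_corr <- matrix(0.45, p, p); diag(latent_corr) <- 1
  }
  if (!all(dim(latent_corr) == c(p, p)))
    stop_validation("latent_corr must be ", p, " x ", p)
  F <- psd_factor(latent_corr)
  if (is.null(names)) names <- paste0("R", seq_len(p))
  with_local_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% F
    thresholds <- stats::qnorm(1 - prevalence)
    X <- sweep(Z, 2, thresholds, `>`) * 1L
    colnames(X) <- names
    y <- intercept + drop(X %*% weights) + stats::rnorm(n, 0, resid_sd)
    data.frame(y = y, X, check.names = FALSE)
  })
}
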