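# Dominant/recessive SNP recoding and the differential-susceptibility
# gene-by-environment model ladder.

#' Dominant and recessive codes for an allele count
#'
#' A SNP scored as the number of plasticity alleles (0, 1 or 2) decomposes
#' into a *dominant* code (at least one allele present) and a *recessive*
#' code (both alleles present):
#' 0 -> (0, 0), 1 -> (1, 0), 2 -> (1, 1).
#' The two codes always sum back to the allele count, and the dominant code
#' is never smaller than the recessive one.  Missing counts propagate.
#'
#' @param count Integer vector of allele counts in \{0, 1, 2\} (NA allowed).
#' @return A data frame with columns `dominant` and `recessive`.
#' @export
code_snp <- function(count) {
  ok <- is.na(count) | count %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok)
    stop_validation("allele counts must be 0, 1, 2 or NA; offending value(s) ",
                    paste(unique(count[bad]), collapse = ", "),
                    " at position(s) ", paste(utils::head(bad, 10),
                                              collapse = ", "))
  }
  data.frame(dominant = as.integer(count >= 1),
             recessive = as.integer(count == 2))
}

#' Gene cumulative-risk scores from a genotype table
#'
#' Recodes every SNP column into its dominant and recessive codes and
#' appends three gene CR indices: `gene_total` (sum of allele counts),
#' `gene_dom` (sum of dominant codes) and `gene_rec` (sum of recessive
#' codes).  By construction `gene_total == gene_dom + gene_rec` row by row.
#'
#' @param g Data frame of allele-count columns in \{0, 1, 2\}; non-SNP
#'   columns may be excluded via `snps`.
#' @param snps SNP column names (default: all numeric columns of `g`).
#' @param na_action `"fail"` (default) or `"listwise"` (drop incomplete rows
#'   with a message).
#' @return A data frame with, for each SNP `s`, columns `<s>d` and `<s>r`,
#'   plus `gene_total`, `gene_dom`, `gene_rec` (and any non-SNP columns of
#'   `g` carried through).
#' @export
gene_scores <- function(g, snps = NULL,
                        na_action = c("fail", "listwise")) {
  na_action <- match.arg(na_action)
  if (!is.data.frame(g)) stop_validation("g must be a data frame")
  if (is.null(snps))
    snps <- names(g)[vapply(g, is.numeric, logical(1))]
  missing_cols <- setdiff(snps, names(g))
  if (length(missing_cols))
    stop_validation("unknown SNP column(s): ",
                    paste(missing_cols, collapse = ", "))
  if (anyDuplicated(snps)) stop_validation("duplicate SNP labels")
  if (anyNA(g[snps])) {
    if (na_action == "fail")
      stop_validation("missing genotypes; use na_action = 'listwise'")
    keep <- stats::complete.cases(g[snps])
    message("listwise deletion: dropped ", sum(!keep), " of ", nrow(g),
            " rows with missing genotypes")
    g <- g[keep, , drop = FALSE]
  }
  out <- g
  dom <- rec <- matrix(0L, nrow(g), length(snps))
  for (j in seq_along(snps)) {
    codes <- tryCatch(code_snp(g[[snps[j]]]), crindex_validation_error =
      function(e) stop_validation("SNP '", snps[j], "': ", conditionMessage(e)))
    dom[, j] <- codes$dominant
    rec[, j] <- codes$recessive
    out[[paste0(snps[j], "d")]] <- codes$dominant
    out[[paste0(snps[j], "r")]] <- codes$recessive
  }
  out$gene_total <- as.integer(rowSums(as.matrix(g[snps])))
  out$gene_dom <- as.integer(rowSums(dom))
  out$gene_rec <- as.integer(rowSums(rec))
  stopifnot(all(out$gene_total == out$gene_dom + out$gene_rec))
  out
}

#' Read a genotype table
#'
#' Tab-separated file with a header: one participant-id column (first column
#' by default) and one integer 0/1/2 column per SNP.
#'
#' @param path File path.
#' @param id_col Name or index of the participant-id column.
#' @return A data frame; the id column is carried as-is.
#' @export
read_genotypes <- function(path, id_col = 1) {
  if (!file.exists(path)) stop_validation("genotype file not found: ", path)
  g <- utils::read.delim(path, check.names = FALSE)
  if (is.numeric(id_col)) id_col <- names(g)[id_col]
  snps <- setdiff(names(g), id_col)
  for (s in snps) {
    if (!is.numeric(g[[s]]))
      stop_validation("SNP column '", s, "' is not numeric")
  }
  g
}

#' Build a differential-susceptibility G x E model ladder
#'
#' Constructs the ordered model specifications for interrogating a gene
#' cumulative-risk index in a G x E design.  The environment column is
#' mean-centered (analysis-sample mean) before any product term is formed,
#' and products are never re-centered afterwards, so a zero gene main effect
#' is a test at the mean of the environment.  Covariates (e.g. a 0/1 sex
#' indicator) are entered as given, never centered.
#'
#' Two gene representations are supported:
#' * `genes = "total"` (4 models): (1) covariates + E + G, (2) adds G x E,
#'   (3) restricts the E main effect to zero (strong differential
#'   susceptibility), (4) additionally restricts the G main effect to zero
#'   (no gene effect at the mean environment).
#' * `genes = "per_snp"` (4 models, numbered 5-8 in reports): per-SNP
#'   dominant/recessive codes replace the total score.  Model 7 carries 19
#'   restrictions (E = 0, all gene codes equal, all G x E products equal);
#'   Model 8 adds the common gene coefficient = 0, giving 20.
#'
#' Fitting the total-score strong-DS models and the per-SNP 19/20-restriction
#' models on the same data yields identical results -- the composite/
#' constraint identity.
#'
#' @param outcome Outcome column name.
#' @param environment Environment column name.
#' @param gene_total Gene total-score column (for `genes = "total"`).
#' @param snp_codes Character vector of per-SNP code columns, dominant codes
#'   then recessive codes (for `genes = "per_snp"`).
#' @param covariates Covariate column names.
#' @param genes `"total"` or `"per_snp"`.
#' @param center_env Mean-center the environment? Default `TRUE`.
#' @param labels Model labels; defaults are `"Model 1"`..`"Model 4"` for the
#'   total representation and `"Model 5"`..`"Model 8"` for per-SNP.
#' @return A named list of `list(spec, restrictions)` suitable for
#'   [run_ladder] on raw data.
#' @export
build_gxe_ladder <- function(outcome, environment, gene_total = NULL,
                             snp_codes = NULL, covariates = character(),
                             genes = c("total", "per_snp"),
                             center_env = TRUE, labels = NULL) {
  genes <- match.arg(genes)
  cov_terms <- lapply(covariates, term_col)
  env_term <- term_col(environment, label = "E", center = center_env)
  if (genes == "total") {
    if (is.null(gene_total))
      stop_validation("genes = 'total' requires gene_total")
    if (is.null(labels)) labels <- paste("Model", 1:4)
    g_term <- term_col(gene_total, label = "G")
    gxe_term <- term_product(gene_total, environment, label = "GxE",
                             center_b = center_env)
    main_terms <- c(cov_terms, list(env_term, g_term))
    full_terms <- c(main_terms, list(gxe_term))
    models <- list(
      list(spec = model_spec(outcome, main_terms), restrictions = NULL),
      list(spec = model_spec(outcome, full_terms), restrictions = NULL),
      list(spec = model_spec(outcome, full_terms),
           restrictions = "E = 0"),
      list(spec = model_spec(outcome, full_terms),
           restrictions = c("E = 0", "G = 0")))
  } else {
    if (is.null(snp_codes) || length(snp_codes) < 2)
      stop_validation("genes = 'per_snp' requires >= 2 snp_codes")
    if (is.null(labels)) labels <- paste("Model", 5:8)
    g_terms <- lapply(snp_codes, term_col)
    prod_labels <- paste0("E:", snp_codes)
    p_terms <- mapply(function(s, lab)
      term_product(environment, s, label = lab, center_a = center_env),
      snp_codes, prod_labels, SIMPLIFY = FALSE)
    main_terms <- c(cov_terms, list(env_term), g_terms)
    full_terms <- c(main_terms, p_terms)
    g_chain <- paste(snp_codes, collapse = " = ")
    p_chain <- paste(prod_labels, collapse = " = ")
    models <- list(
      list(spec = model_spec(outcome, main_terms), restrictions = NULL),
      list(spec = model_spec(outcome, full_terms), restrictions = NULL),
      list(spec = model_spec(outcome, full_terms),
           restrictions = c("E = 0", g_chain, p_chain)),
      list(spec = model_spec(outcome, full_terms),
           restrictions = c("E = 0", g_chain,
                            paste(snp_codes[1], "= 0"), p_chain)))
  }
  names(models) <- labels
  models
}
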