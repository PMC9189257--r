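Package: crindex
Title: Interrogating Cumulative Risk Indices by Restricted Least Squares
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for severely testing ("interrogating") the weighting
    schemes behind cumulative risk (CR) indices in developmental and
    genetic epidemiology.  Fits ordinary and linearly restricted least
    squares either from raw data or from published summary moments
    (correlation matrix, means, SDs, N), reports per-restriction
    Lagrange-multiplier tests, nested-model F comparisons, and
    fit/parsimony indices (adjusted R-squared, Schwarz BIC).  Includes
    dominant/recessive recoding of 0/1/2 SNP allele counts, construction
    of gene-by-environment differential-susceptibility model ladders,
    composite-versus-constraint equivalence checks, and seed-deterministic
    synthetic data generators (exact moment matching, latent-threshold
    risk indicators, Hardy-Weinberg genotypes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
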