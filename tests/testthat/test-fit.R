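# Fits from the packaged verbal-IQ summary table are checked against the
# published regression results at their printed precision.

test_that("single-predictor fit reproduces published coefficients and indices", {
  f <- fit_ols(table2, model_spec("VIQ", "Occ"))
  co <- f$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 107.31, tolerance = 0.01)
  expect_equal(co$se[co$term == "(Intercept)"], 1.11, tolerance = 0.01)
  expect_equal(co$estimate[co$term == "Occ"], -26.55, tolerance = 0.01)
  expect_equal(co$se[co$term == "Occ"], 2.49, tolerance = 0.01)
  expect_equal(f$r2, 0.348, tolerance = 0.001)
  expect_equal(unname(f$fstatistic),
               c(113.74, 1, 213), tolerance = 0.01)
  expect_equal(f$sbc, 1160.61, tolerance = 0.01)
  idx <- fit_indices(f)
  expect_equal(idx$sbc, f$sbc)
  expect_equal(idx$adj_r2, 0.345, tolerance = 0.001)
})

test_that("ten-predictor fit matches the published full model", {
  f <- fit_ols(table2, spec_m2)
  expect_equal(f$r2, 0.519, tolerance = 0.001)
  published <- c(Occ = -10.82, Educ = -6.92, Eth = -6.17, Inter = -9.38,
                 Ment = 2.05, Fam = -1.82, Life = -3.78, Pers = -4.02,
                 Sup = -1.57, Anx = -1.77)
  co <- f$coefficients
  est <- setNames(co$estimate, co$term)[names(published)]
  expect_equal(unname(est), unname(published), tolerance = 0.011)
  # only the first four indicators are individually significant
  tt <- setNames(abs(co$t), co$term)[names(published)]
  expect_identical(unname(tt > 1.98),
                   c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)))
})

test_that("all-slopes-equal restricted fit matches the published model", {
  f <- fit_restricted(table2, spec_m2, restr_all_equal)
  co <- f$coefficients
  slopes <- co[co$term != "(Intercept)", ]
  # all tied terms report the same estimate and the same SE
  expect_equal(length(unique(round(slopes$estimate, 10))), 1L)
  expect_equal(length(unique(round(slopes$se, 10))), 1L)
  expect_equal(slopes$estimate[1], -4.65, tolerance = 0.01)
  expect_equal(slopes$se[1], 0.36, tolerance = 0.005)
  expect_equal(f$r2, 0.442, tolerance = 0.005)
  expect_equal(f$k_free, 2L)
  expect_false(any(slopes$free))
  rt <- f$restriction_tests
  expect_identical(nrow(rt), 9L)
  expect_identical(unique(rt$df), 213L)
  # printed Lagrange-multiplier estimates, SEs and t ratios
  expect_equal(rt$estimate,
               c(-151.9, -272.5, -472.6, -614.8, -268.7, -227.1, -149.9,
                 -265.2, -189.5), tolerance = 0.005)
  expect_equal(rt$se,
               c(53.1, 89.4, 125.4, 124.8, 104.5, 106.8, 93.2, 99.4, 72.3),
               tolerance = 0.005)
  expect_equal(rt$t,
               c(-2.86, -3.05, -3.77, -4.92, -2.57, -2.13, -1.60, -2.67,
                 -2.62), tolerance = 0.02)
  # 8 of the 9 constraint tests are significant at .05
  expect_identical(sum(rt$p < 0.05), 8L)
})

test_that("two-group restricted fit matches the published model", {
  f <- fit_restricted(table2, spec_m2, restr_two_group)
  co <- f$coefficients
  expect_equal(co$estimate[co$term == "Occ"], -8.60, tolerance = 0.01)
  expect_equal(co$se[co$term == "Occ"], 0.83, tolerance = 0.01)
  expect_equal(co$estimate[co$term == "Anx"], -1.43, tolerance = 0.01)
  expect_equal(co$se[co$term == "Anx"], 0.71, tolerance = 0.01)
  expect_equal(f$r2, 0.505, tolerance = 0.001)
  expect_equal(f$adj_r2, 0.500, tolerance = 0.001)
  expect_equal(f$sbc, 1106.79, tolerance = 0.05)
  expect_identical(sum(f$restriction_tests$p < 0.05), 0L)
})

test_that("restricting a coefficient to its own estimate changes nothing", {
  free <- fit_ols(table2, spec_m2)
  b_occ <- free$coefficients$estimate[free$coefficients$term == "Occ"]
  f <- fit_restricted(table2, spec_m2,
                      sprintf("Occ = %.15g", b_occ))
  expect_equal(f$sse, free$sse, tolerance = 1e-8)
  expect_equal(f$restriction_tests$estimate, 0, tolerance = 1e-6)
  expect_equal(f$coefficients$estimate, free$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("restricted fits equal the reparameterization brute-force oracle", {
  for (case in 1:12) {
    n <- 30 + case * 10
    p <- 2 + (case %% 6)
    d <- random_problem(n, p, seed = 100 + case)
    labels <- paste0("x", seq_len(p))
    spec <- model_spec("y", labels)
    # alternate between equality chains, zero and general restrictions
    rs <- switch(1 + case %% 3,
                 paste(labels[1:2], collapse = " = "),
                 paste(labels[p], "= 0"),
                 sprintf("2*%s - %s = 0.5", labels[1], labels[2]))
    restr <- parse_restrictions(rs, spec)
    fit <- fit_restricted(d, spec, restr)
    orc <- oracle_restricted(d$y, as.matrix(d[labels]), restr$L, restr$c)
    expect_equal(fit$coefficients$estimate, orc$beta, tolerance = 1e-10)
    expect_equal(fit$sse, orc$sse, tolerance = 1e-10)
    # a restriction can never reduce the error sum of squares
    expect_gte(fit$sse, fit_ols(d, spec)$sse - 1e-10)
  }
})

test_that("raw-data fits agree with hand calculations and degenerate cases", {
  toy <- data.frame(y = c(1, 2, 3, 4), x = c(0, 0, 1, 1))
  f <- fit_from_raw(toy, model_spec("y", "x"))
  expect_equal(f$coefficients$estimate,
               c(1.5, 2.0), tolerance = 1e-12)
  # intercept-only model
  f0 <- fit_from_raw(toy, model_spec("y", character()))
  expect_equal(f0$coefficients$estimate, mean(toy$y))
  expect_equal(f0$r2, 0)
  expect_identical(f0$k_free, 1L)
})

test_that("summary-path and raw-path fits agree on exact-moment samples", {
  samp <- exact_moment_sample(table2, seed = 3)
  f_sum <- fit_ols(table2, spec_m2)
  f_raw <- fit_from_raw(samp, spec_m2)
  expect_equal(f_raw$coefficients$estimate, f_sum$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f_raw$coefficients$se, f_sum$coefficients$se,
               tolerance = 1e-8)
  expect_equal(f_raw$r2, f_sum$r2, tolerance = 1e-8)
  expect_equal(f_raw$sse, f_sum$sse, tolerance = 1e-6)
})

test_that("a predictor orthogonal to everything gets slope zero", {
  set.seed(42)
  m <- summary_moments(c("y", "a", "b"), 100, c(0, 0, 0), c(1, 1, 1),
                       matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 1), 3))
  f <- fit_ols(m, model_spec("y", c("a", "b")))
  expect_equal(f$coefficients$estimate[f$coefficients$term == "b"], 0,
               tolerance = 1e-12)
  f_drop <- fit_ols(m, model_spec("y", "a"))
  expect_equal(f$r2, f_drop$r2, tolerance = 1e-12)
})

test_that("singular designs fail naming a dependent column set", {
  d <- random_problem(50, 3, seed = 9)
  d$x4 <- d$x1 + d$x2
  expect_error(fit_from_raw(d, model_spec("y", paste0("x", 1:4))),
               class = "crindex_numeric_error")
  err <- tryCatch(fit_from_raw(d, model_spec("y", paste0("x", 1:4))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "linearly dependent")
})

test_that("composite terms can be fitted from summary moments, products cannot", {
  spec_comp <- model_spec("VIQ", term_composite(risk_names, label = "CR10"))
  f <- fit_ols(table2, spec_comp)
  expect_equal(f$r2, 0.442, tolerance = 0.005)
  spec_prod <- model_spec("VIQ", term_product("Occ", "Educ"))
  expect_error(fit_ols(table2, spec_prod), "cannot be formed from summary")
})
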