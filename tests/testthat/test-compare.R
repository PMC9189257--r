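test_that("nested F tests reproduce the published model comparisons", {
  f2 <- fit_ols(table2, spec_m2)
  f3 <- fit_restricted(table2, spec_m2, restr_all_equal)
  f4 <- fit_restricted(table2, spec_m2, restr_two_group)

  c23 <- compare_nested(f2, f3)
  expect_identical(c(c23$df1, c23$df2), c(9L, 204L))
  expect_equal(c23$f, 3.66, tolerance = 0.005)
  expect_equal(c23$p, 0.0003, tolerance = 0.1)

  c24 <- compare_nested(f2, f4)
  expect_identical(c(c24$df1, c24$df2), c(8L, 204L))
  expect_equal(c24$f, 0.74, tolerance = 0.02)
  expect_equal(c24$p, 0.66, tolerance = 0.05)

  c43 <- compare_nested(f4, f3)
  expect_identical(c(c43$df1, c43$df2), c(1L, 212L))
  expect_equal(c43$f, 27.21, tolerance = 0.005)

  expect_error(compare_nested(f3, f2), "fewer free parameters")
})

test_that("R-squared and SSE forms of the nested F are identical", {
  f2 <- fit_ols(table2, spec_m2)
  f3 <- fit_restricted(table2, spec_m2, restr_all_equal)
  cmp <- compare_nested(f2, f3)
  f_sse <- ((f3$sse - f2$sse) / cmp$df1) / (f2$sse / cmp$df2)
  expect_equal(cmp$f, f_sse, tolerance = 1e-12)
})

test_that("an inactive restriction gives F = 0, p = 1", {
  free <- fit_ols(table2, spec_m2)
  b_occ <- free$coefficients$estimate[free$coefficients$term == "Occ"]
  f_inact <- fit_restricted(table2, spec_m2, sprintf("Occ = %.15g", b_occ))
  cmp <- compare_nested(free, f_inact)
  expect_equal(cmp$f, 0, tolerance = 1e-10)
  expect_equal(cmp$p, 1, tolerance = 1e-10)
})

test_that("single-restriction t and nested F measure the same SSE increase", {
  # the Lagrange t scales the restriction's SSE increase by the restricted
  # model's mean square, the nested F by the full model's; both recover
  # delta-SSE exactly, so t^2 * MSE_r == F * MSE_f
  for (case in 1:8) {
    d <- random_problem(60, 4, seed = 300 + case)
    spec <- model_spec("y", paste0("x", 1:4))
    rs <- if (case %% 2) "x1 = x2" else "x3 = 0"
    full <- fit_ols(d, spec)
    restr <- fit_restricted(d, spec, rs)
    cmp <- compare_nested(full, restr)
    delta_sse <- restr$sse - full$sse
    expect_equal(restr$restriction_tests$t^2 * restr$sigma2, delta_sse,
                 tolerance = 1e-10)
    expect_equal(cmp$f * full$sigma2, delta_sse, tolerance = 1e-10)
  }
})

test_that("three-principles report matches the published verdicts", {
  f2 <- fit_ols(table2, spec_m2)
  f3 <- fit_restricted(table2, spec_m2, restr_all_equal)
  f4 <- fit_restricted(table2, spec_m2, restr_two_group)

  pr4 <- principles_report(f2, f4)
  expect_true(pr4$p1$pass)
  expect_true(pr4$p2$pass)
  expect_identical(pr4$p2$n_tests, 8L)
  expect_identical(pr4$recommendation, "accept restricted")
  expect_gt(pr4$p3$delta_adj_r2, 0)
  expect_lt(pr4$p3$delta_sbc, 0)
  # SEs of shared terms shrink under the accepted restrictions
  expect_true(all(pr4$p3$se_change$se_restricted <
                    pr4$p3$se_change$se_full))

  pr3 <- principles_report(f2, f3)
  expect_false(pr3$p1$pass)
  expect_false(pr3$p2$pass)
  expect_identical(length(pr3$p2$significant), 8L)
  expect_identical(pr3$recommendation, "reject restricted")

  # no effective restriction: vacuous pass
  pr0 <- principles_report(f2, f2)
  expect_true(pr0$p1$pass && pr0$p2$pass)
  expect_identical(pr0$recommendation, "accept restricted")
})

test_that("ladders rank models and flag the SBC optimum", {
  models <- list(
    "Model 1" = list(spec = model_spec("VIQ", "Occ")),
    "Model 2" = list(spec = spec_m2),
    "Model 3" = list(spec = spec_m2, restrictions = restr_all_equal),
    "Model 4" = list(spec = spec_m2, restrictions = restr_two_group))
  lad <- run_ladder(table2, models, baseline = "Model 2")
  expect_identical(lad$sbc_optimal, "Model 4")
  expect_equal(lad$table$r2, c(0.348, 0.519, 0.442, 0.505),
               tolerance = 0.002)
  expect_identical(lad$principles[["Model 4"]]$recommendation,
                   "accept restricted")
  expect_identical(lad$principles[["Model 3"]]$recommendation,
                   "reject restricted")
  # baseline row has no comparison; restricted rows do
  expect_true(is.na(lad$table$f_vs_baseline[lad$table$model == "Model 2"]))
  expect_false(anyNA(lad$table$f_vs_baseline[lad$table$model %in%
                                               c("Model 3", "Model 4")]))
  expect_error(run_ladder(table2, models[1]), ">= 2 models")
  expect_error(run_ladder(table2, setNames(models, c("a", "a", "b", "c"))),
               "duplicate model labels")
})

test_that("restriction count orders explained variance along a nested chain", {
  for (case in 1:5) {
    d <- random_problem(80, 5, seed = 400 + case)
    spec <- model_spec("y", paste0("x", 1:5))
    r2s <- c(
      fit_ols(d, spec)$r2,
      fit_restricted(d, spec, "x1 = x2")$r2,
      fit_restricted(d, spec, c("x1 = x2", "x3 = x4"))$r2,
      fit_restricted(d, spec, c("x1 = x2 = x3 = x4 = x5"))$r2)
    expect_true(all(diff(r2s[1:3]) <= 1e-12))
    expect_lte(r2s[4], r2s[1] + 1e-12)
  }
})
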