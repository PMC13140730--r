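test_that("constant response gives a flagged boundary fit", {
  d <- simulate_lmm_dataset(4, 3, seed = 1)
  d$y <- 5
  f <- fit_lmm(d, "y", fixed = "genotype")
  expect_false(f$converged)
  expect_equal(unname(f$varcomp), c(0, 0))
  expect_true(all(is.na(f$f_table$F)))
})

test_that("with one clip per mouse the fit matches ordinary least squares", {
  d <- simulate_lmm_dataset(8, 1, genotype_effect = 1.5, seed = 3)
  f <- fit_lmm(d, "y", fixed = "genotype")
  ols <- lm(y ~ genotype, data = d)
  expect_equal(unname(f$coefficients[, "Estimate"]),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("Kenward-Roger df equals the classical value in balanced designs", {
  d <- simulate_lmm_dataset(9, 5, genotype_effect = 1, mouse_sd = 2,
                            seed = 7)
  f <- fit_lmm(d, "y", fixed = "genotype")
  kr <- kr_f_test(f, "genotype")
  expect_equal(kr$df1, 1)
  expect_equal(kr$df2, 16)          # 18 mice - 2 between-mouse parameters

  # oracle: ANOVA on mouse means gives the same F and p
  mm <- aggregate(y ~ mouse_id + genotype, d, mean)
  a <- anova(lm(y ~ genotype, mm))
  expect_equal(kr$F, a["genotype", "F value"], tolerance = 1e-6)
  expect_equal(kr$p, a["genotype", "Pr(>F)"], tolerance = 1e-6)
  expect_equal(a["Residuals", "Df"], 16)
})

test_that("KR df stays in the animals-to-clips bracket at the boundary", {
  # with zero true mouse variance the fit is singular, yet KR still
  # reproduces the exact balanced-design test: df2 = mouse-level df, and
  # always lies between (n_mice - rank) and (n_clips - rank)
  d <- simulate_lmm_dataset(9, 5, mouse_sd = 0, resid_sd = 1, seed = 11)
  f <- fit_lmm(d, "y", fixed = "genotype")
  kr <- kr_f_test(f, "genotype")
  expect_gte(kr$df2, 16 - 1e-6)
  expect_lte(kr$df2, 88 + 1e-6)
  expect_equal(kr$df2, 16, tolerance = 1e-6)
})

test_that("duplicating every clip changes F but not the estimates", {
  d <- simulate_lmm_dataset(6, 3, genotype_effect = 2, seed = 5)
  f1 <- fit_lmm(d, "y", fixed = "genotype")
  f2 <- fit_lmm(rbind(d, d), "y", fixed = "genotype")
  expect_equal(f1$coefficients[, "Estimate"],
               f2$coefficients[, "Estimate"], tolerance = 1e-4)
  expect_false(isTRUE(all.equal(kr_f_test(f1, "genotype")$F,
                                kr_f_test(f2, "genotype")$F)))
})

test_that("aliased fixed effects are named in the error", {
  d <- simulate_lmm_dataset(4, 3, seed = 2)
  d$dup <- d$genotype
  expect_error(fit_lmm(d, "y", fixed = c("genotype", "dup")),
               "aliased")
})

test_that("Kenward-Roger tests require REML", {
  d <- simulate_lmm_dataset(4, 3, seed = 2)
  f <- fit_lmm(d, "y", fixed = "genotype", reml = FALSE)
  expect_error(kr_f_test(f, "genotype"), "REML")
})

test_that("MANOVA reduces to univariate ANOVA for one response", {
  d <- simulate_lmm_dataset(10, 3, genotype_effect = 1, seed = 9)
  mv <- fit_manova(d, "y", "genotype")
  a <- anova(lm(y ~ genotype, d))
  expect_equal(mv$genotype$F, a["genotype", "F value"])
  expect_equal(mv$genotype$p, a["genotype", "Pr(>F)"])
})

test_that("MANOVA effect sizes track simulated multivariate shifts", {
  set.seed(13)
  n <- 60
  d <- data.frame(genotype = rep(c("wildtype", "reeler"), each = n / 2),
                  sex = rep(c("F", "M"), n / 2))
  for (v in c("a", "b", "c")) d[[v]] <- rnorm(n)
  d$a <- d$a + ifelse(d$genotype == "reeler", 2.5, 0)
  d$b <- d$b + ifelse(d$genotype == "reeler", 1.5, 0)
  mv <- fit_manova(d, c("a", "b", "c"), c("genotype", "sex"))
  expect_equal(mv$genotype$size_class, "large")
  expect_gte(mv$genotype$eta_sq_p, 0.14)
  expect_lt(mv$sex$eta_sq_p, 0.06)  # null factor stays small
  # collinear responses are refused
  d$dup <- d$a
  expect_error(fit_manova(d, c("a", "dup"), "genotype"), "collinear")
})

test_that("effect-size banding is the printed lower-inclusive step rule", {
  expect_equal(classify_effect_size(0.549), "large")
  expect_equal(classify_effect_size(0.006), "negligible")
  expect_equal(classify_effect_size(0.06), "medium")
  expect_equal(classify_effect_size(0.01), "small")
  expect_equal(classify_effect_size(0.14), "large")
  expect_equal(classify_effect_size(0.0099), "negligible")
  expect_error(classify_effect_size(1.2), "0, 1")
  # monotone step function over a grid
  g <- seq(0, 1, by = 0.001)
  cls <- classify_effect_size(g)
  ranks <- c(negligible = 1, small = 2, medium = 3, large = 4)[cls]
  expect_true(all(diff(ranks) >= 0))
})

test_that("chi-squared on zone tables matches the hand formula", {
  tab <- matrix(c(12, 30, 18, 20, 25, 15), nrow = 2, byrow = TRUE)
  res <- chi_square_zones(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 2)            # (2-1)(3-1)
  expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))

  same <- matrix(c(30, 40, 30, 30, 40, 30), 2, byrow = TRUE)
  res2 <- chi_square_zones(same)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  t22 <- matrix(c(7, 13, 11, 9), 2)
  res3 <- chi_square_zones(t22)
  E3 <- outer(rowSums(t22), colSums(t22)) / sum(t22)
  expect_equal(res3$statistic, sum((t22 - E3)^2 / E3), tolerance = 1e-10)
  expect_equal(res3$df, 1)

  expect_warning(chi_square_zones(matrix(c(30.5, 40.5, 29, 32, 38, 30),
                                         2, byrow = TRUE)), "counts")
  expect_error(chi_square_zones(matrix(c(0, 0, 5, 5), 2)), "expected")
})

test_that("two-level post hoc equals the unadjusted comparison", {
  d <- simulate_lmm_dataset(6, 4, sessions = c("OF", "H1"),
                            session_effects = c(H1 = -2), seed = 15)
  f <- fit_lmm(d, "y", fixed = c("genotype", "session"))
  ph_t <- posthoc_pairwise(f, "session", adjust = "tukey")
  ph_n <- posthoc_pairwise(f, "session", adjust = "none")
  expect_equal(ph_t$contrasts$p.value, ph_n$contrasts$p.value,
               tolerance = 1e-9)
  expect_error(posthoc_pairwise(f, "notafactor"), "not in the model")
})

test_that("post hoc contrasts recover a simulated session ordering", {
  d <- simulate_lmm_dataset(9, 5, sessions = c("OF", "H1", "H5"),
                            session_effects = c(H1 = -1.5, H5 = -2),
                            mouse_sd = 1.5, resid_sd = 1, seed = 17)
  f <- fit_lmm(d, "y", fixed = c("genotype", "session"))
  ph <- posthoc_pairwise(f, "session")
  est <- setNames(ph$contrasts$estimate, ph$contrasts$contrast)
  expect_gt(est[["OF - H1"]], 0)
  expect_gt(est[["OF - H5"]], 0)
  expect_gt(est[["H1 - H5"]], 0)
  emm <- setNames(ph$emmeans$emmean, as.character(ph$emmeans$session))
  expect_true(emm[["OF"]] > emm[["H1"]] && emm[["H1"]] > emm[["H5"]])
})

test_that("pairwise family-wise error stays near nominal under the null", {
  set.seed(19)
  hits <- vapply(1:60, function(i) {
    d <- simulate_lmm_dataset(6, 3, sessions = c("OF", "H1", "H5"),
                              mouse_sd = 1, resid_sd = 1)
    f <- fit_lmm(d, "y", fixed = "session")
    any(posthoc_pairwise(f, "session")$contrasts$p.value < 0.05)
  }, TRUE)
  # 95% binomial upper band around 0.05 at 60 replicates
  expect_lte(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 60) + 1e-9)
})

test_that("residual normality diagnostics flag heavy tails only", {
  d <- simulate_lmm_dataset(8, 5, mouse_sd = 1, resid_sd = 1, seed = 23)
  f <- fit_lmm(d, "y", fixed = "genotype")
  r <- check_residual_normality(f)
  expect_true(r$assessable)
  expect_true(r$normal)

  d2 <- d
  set.seed(24)
  d2$y <- d2$y + 3 * stats::rt(nrow(d2), df = 1)   # heavy-tailed noise
  f2 <- fit_lmm(d2, "y", fixed = "genotype")
  expect_false(check_residual_normality(f2)$normal)

  d3 <- d; d3$y <- 7
  f3 <- fit_lmm(d3, "y", fixed = "genotype")
  expect_false(check_residual_normality(f3)$assessable)
})
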