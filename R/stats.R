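#' Fit a random-intercept linear mixed model for one whisker metric
#'
#' REML fit of `response ~ fixed effects + (1 | mouse)`, with each video
#' clip contributing one observation. Clips from the same animal are not
#' independent, which the mouse-level random intercept absorbs; F-tests on
#' the fixed effects then use the Kenward-Roger small-sample approximation,
#' whose denominator degrees of freedom land between the number of animals
#' and the number of clips.
#'
#' @param data data.frame of per-clip metric rows plus design columns
#' @param response column name of the outcome metric
#' @param fixed character vector of fixed-effect terms (may include
#'   interactions, e.g. `"genotype * session"`)
#' @param grouping column name of the animal identifier
#' @param reml use REML (required for Kenward-Roger tests)
#' @param kr compute the Kenward-Roger F table (set `FALSE` to skip the
#'   adjustment when only estimates and standard errors are needed)
#' @return an `lmm_result` list: `model` (the lmerMod), `coefficients`
#'   (estimates and standard errors), `varcomp` (mouse-intercept and
#'   residual variances), `f_table` (Kenward-Roger type-III F tests),
#'   `converged`, `singular`, `residuals`
#' @export
fit_lmm <- function(data, response, fixed = c("genotype", "sex", "age_group"),
                    grouping = "mouse_id", reml = TRUE, kr = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            grouping %in% names(data))
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  for (nm in names(d))
    if (is.character(d[[nm]])) d[[nm]] <- factor(d[[nm]])
  if (length(unique(d[[grouping]])) < 2L)
    stop("need at least 2 animals to separate mouse and residual variance")

  fixed_rhs <- paste(fixed, collapse = " + ")
  mm <- model.matrix(as.formula(paste("~", fixed_rhs)), d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(d) < qrm$rank + 2L)
    stop("too few non-missing rows for the fixed-effect design")

  fml <- as.formula(paste(response, "~", fixed_rhs, "+ (1 |", grouping, ")"))
  if (var(d[[response]]) == 0) {
    terms <- attr(stats::terms(as.formula(paste("~", fixed_rhs))),
                  "term.labels")
    ft <- data.frame(term = terms, F = NA_real_, df1 = NA_real_,
                     df2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(model = NULL, formula = fml, coefficients = NULL,
                          varcomp = c(mouse = 0, residual = 0),
                          f_table = ft, converged = FALSE, singular = TRUE,
                          residuals = rep(0, nrow(d)), reml = reml,
                          n_obs = nrow(d),
                          n_groups = length(unique(d[[grouping]])),
                          message = paste("response is constant: boundary",
                                          "fit, F tests undefined")),
                     class = "lmm_result"))
  }

  # nobs-vs-levels checks relaxed so one-clip-per-mouse designs fit (the
  # random intercept is then confounded with the residual; estimates match
  # the ordinary fixed-effects fit)
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = d, REML = reml, control = ctrl),
    warning = function(w) invokeRestart("muffleWarning"))
  converged <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0L

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(mouse = vc$vcov[vc$grp == grouping],
               residual = vc$vcov[vc$grp == "Residual"])
  cf <- summary(fit)$coefficients

  ft <- if (reml && kr) {
    a <- suppressMessages(stats::anova(fit, type = 3,
                                       ddf = "Kenward-Roger"))
    data.frame(term = rownames(a), F = a[["F value"]], df1 = a$NumDF,
               df2 = a$DenDF, p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
  } else NULL

  structure(list(model = fit, formula = fml,
                 coefficients = cf, varcomp = varcomp, f_table = ft,
                 converged = converged,
                 singular = lme4::isSingular(fit),
                 residuals = residuals(fit), reml = reml,
                 n_obs = nrow(d),
                 n_groups = length(unique(d[[grouping]])),
                 message = if (converged) "" else
                   paste(fit@optinfo$conv$lme4$messages, collapse = "; ")),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> ", deparse(x$formula), "\n", sep = "")
  cat("  ", x$n_obs, " clips from ", x$n_groups, " mice; variance: mouse ",
      signif(x$varcomp["mouse"], 4), ", residual ",
      signif(x$varcomp["residual"], 4), "\n", sep = "")
  if (!is.null(x$f_table)) print(x$f_table, row.names = FALSE)
  if (!x$converged) cat("  NOT converged: ", x$message, "\n", sep = "")
  invisible(x)
}

#' Kenward-Roger F-test for one fixed-effect term
#'
#' @param fit an [fit_lmm()] result (must be a REML fit)
#' @param term fixed-effect term name as it appears in the model
#' @return list with `F`, `df1`, `df2` (fractional), `p`
#' @export
kr_f_test <- function(fit, term) {
  stopifnot(inherits(fit, "lmm_result"))
  if (!fit$reml)
    stop("Kenward-Roger tests are defined for REML fits only")
  if (is.null(fit$f_table))
    stop("no F table on this fit; refit with kr = TRUE")
  i <- match(term, fit$f_table$term)
  if (is.na(i))
    stop("term '", term, "' not in the model; available: ",
         paste(fit$f_table$term, collapse = ", "))
  as.list(fit$f_table[i, c("F", "df1", "df2", "p")])
}

#' Pairwise post hoc contrasts on estimated marginal means
#'
#' Estimated marginal means per factor level with Tukey-adjusted all-pairs
#' comparisons (switchable to "none" or "bonferroni"); degrees of freedom
#' use the Kenward-Roger approximation, matching the omnibus tests.
#'
#' @param fit an [fit_lmm()] result
#' @param factor factor name (or character vector of factors) in the model
#' @param adjust p-value adjustment: "tukey", "bonferroni" or "none"
#' @return list with `emmeans` and `contrasts` data.frames
#' @export
posthoc_pairwise <- function(fit, factor, adjust = "tukey") {
  stopifnot(inherits(fit, "lmm_result"), !is.null(fit$model))
  dat <- fit$model@frame
  for (f in factor) {
    if (!f %in% names(dat)) stop("factor '", f, "' not in the model")
    if (length(unique(dat[[f]])) < 2L)
      stop("factor '", f, "' has a single level; no pairwise contrasts")
  }
  emm <- emmeans::emmeans(fit$model, specs = factor,
                          lmer.df = "kenward-roger")
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  list(emmeans = as.data.frame(emm), contrasts = as.data.frame(prs))
}

#' MANOVA over the whisker metrics with partial eta-squared
#'
#' Multivariate analysis of the outcome metrics against the design factors
#' using the Pillai trace, with an approximate F per factor. Partial
#' eta-squared is computed from the multivariate statistic as
#' `Pillai / s`, `s = min(hypothesis df, number of responses)`, and classed
#' by [classify_effect_size()]. Observations are clip-level by default; the
#' animal identity is not a term of the classical MANOVA, so a mouse-mean
#' aggregation mode is offered for a conservative alternative.
#'
#' @param data per-clip metric rows plus design columns
#' @param responses character vector of response column names
#' @param factors character vector of factor column names (additive model)
#' @param aggregate "clip" (default) or "mouse" (average clips per mouse
#'   within factor cells first)
#' @param grouping animal id column, used by the "mouse" mode
#' @param bands an [effect_size_bands()]
#' @return named list of `manova_result` entries, one per factor, each with
#'   `pillai`, `F`, `df1`, `df2`, `p`, `eta_sq_p`, `size_class`
#' @export
fit_manova <- function(data, responses, factors,
                       aggregate = c("clip", "mouse"),
                       grouping = "mouse_id",
                       bands = effect_size_bands()) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(responses %in% names(data)), all(factors %in% names(data)))
  d <- data[complete.cases(data[, c(responses, factors)]), , drop = FALSE]
  if (aggregate == "mouse") {
    d <- stats::aggregate(d[responses],
                          by = d[c(grouping, factors)], FUN = mean)
  }
  for (f in factors) d[[f]] <- factor(d[[f]])
  Y <- as.matrix(d[responses])
  if (length(responses) > 1L &&
      qr(scale(Y, scale = FALSE))$rank < ncol(Y))
    stop("response variables are collinear to machine precision")

  fml <- as.formula(paste("Y ~", paste(factors, collapse = " + ")))
  res <- list()

  if (length(responses) == 1L) {
    # one response: Pillai-based F reduces exactly to the univariate ANOVA F
    d$.y <- as.numeric(Y)
    a <- anova(aov(as.formula(paste(".y ~", paste(factors, collapse = "+"))),
                   data = d))
    sse <- a["Residuals", "Sum Sq"]; dfe <- a["Residuals", "Df"]
    for (f in factors) {
      ssh <- a[f, "Sum Sq"]; dfh <- a[f, "Df"]
      v <- ssh / (ssh + sse)
      res[[f]] <- manova_result(v, a[f, "F value"], dfh, dfe,
                                a[f, "Pr(>F)"], eta = v, bands)
    }
    return(res)
  }

  m <- stats::manova(fml, data = cbind(d, Y = I(Y)))
  sm <- summary(m, test = "Pillai")$stats
  rn <- trimws(rownames(sm))
  for (f in factors) {
    i <- match(f, rn)
    v <- sm[i, "Pillai"]
    s <- min(sm[i, "Df"], ncol(Y))
    res[[f]] <- manova_result(v, sm[i, "approx F"], sm[i, "num Df"],
                              sm[i, "den Df"], sm[i, "Pr(>F)"],
                              eta = v / s, bands)
  }
  res
}

manova_result <- function(pillai, Fv, df1, df2, p, eta, bands) {
  structure(list(pillai = unname(pillai), F = unname(Fv),
                 df1 = unname(df1), df2 = unname(df2), p = unname(p),
                 eta_sq_p = unname(eta),
                 size_class = classify_effect_size(eta, bands)),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "<manova_result> Pillai = %.4f, F(%g, %g) = %.3f, p = %.4g, eta2p = %.3f (%s)\n",
    x$pillai, x$df1, x$df2, x$F, x$p, x$eta_sq_p, x$size_class))
  invisible(x)
}

#' Classify a partial eta-squared into conventional size bands
#'
#' Lower-inclusive step function: values at or above 0.14 are "large",
#' 0.06 "medium", 0.01 "small", below that "negligible".
#'
#' @param eta_sq_p partial eta-squared value(s) in `[0, 1]`
#' @param bands an [effect_size_bands()]
#' @return character vector of class labels
#' @export
classify_effect_size <- function(eta_sq_p, bands = effect_size_bands()) {
  stopifnot(inherits(bands, "effect_size_bands"))
  if (any(!is.finite(eta_sq_p)) || any(eta_sq_p < 0) || any(eta_sq_p > 1))
    stop("partial eta-squared must lie in [0, 1]")
  ifelse(eta_sq_p >= bands$large, "large",
         ifelse(eta_sq_p >= bands$medium, "medium",
                ifelse(eta_sq_p >= bands$small, "small", "negligible")))
}

#' Pearson chi-squared test on a genotype-by-zone table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = (r - 1)(c - 1)` and no
#' continuity correction, applied to the table exactly as supplied. Zone
#' timings are usually available only as percentages of session time (one
#' overhead video per session); the test is then run on the percentage table
#' as given, with a warning that percentages are not counts — a count-based
#' table can be supplied instead.
#'
#' @param tab nonnegative matrix, rows = genotypes, columns = zones
#' @return list with `statistic`, `df`, `p_value`, `expected`
#' @export
chi_square_zones <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(is.numeric(tab), all(tab >= 0), nrow(tab) >= 2L, ncol(tab) >= 2L)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected cell count")
  if (any(abs(tab - round(tab)) > 1e-8))
    warning("table values are not counts (percentages?); ",
            "the chi-squared sampling model assumes counts")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Residual-normality diagnostic for a fitted mixed model
#'
#' Shapiro-Wilk test and a QQ straightness summary on the conditional
#' residuals. Advisory only: the result never gates the pipeline.
#'
#' @param fit an [fit_lmm()] result
#' @param alpha flag level for the advisory verdict
#' @return list with `assessable`, `shapiro_w`, `p_value`,
#'   `qq_correlation`, and the advisory `normal`
#' @export
check_residual_normality <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "lmm_result"))
  r <- fit$residuals
  if (length(r) < 3L) stop("need at least 3 residuals")
  if (sd(r) == 0)
    return(list(assessable = FALSE, shapiro_w = NA_real_,
                p_value = NA_real_, qq_correlation = NA_real_,
                normal = NA))
  if (length(r) > 5000L) r <- sample(r, 5000L)
  sw <- shapiro.test(r)
  qq <- stats::cor(sort(r), qnorm(stats::ppoints(length(r))))
  list(assessable = TRUE, shapiro_w = unname(sw$statistic),
       p_value = sw$p.value, qq_correlation = qq,
       normal = sw$p.value > alpha)
}
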