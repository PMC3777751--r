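# Group-level statistical battery: summary t-tests, chi-square frequency
# tests, dummy-coded group regression with planned contrasts, partial
# correlation, and hierarchical stepwise regression. All tests two-sided;
# listwise deletion of missing values; no multiple-testing correction
# (planned comparisons).

#' Pooled two-sample t-test from summary statistics
#'
#' Classical pooled-variance two-sample t computed from group means,
#' standard deviations and sizes (as printed in demographic tables), with
#' `df = n1 + n2 - 2` and a two-sided p value. Antisymmetric: swapping the
#' groups flips the sign of t.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of a 2x2 frequency table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_frequencies <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero marginal")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Dummy-coded group regression with planned contrasts vs the reference
#'
#' OLS of the outcome on three group dummies (reference group omitted) and,
#' optionally, age. Reports the overall model F, the partial F for the
#' group dummy block, and for each non-reference group the model-based
#' contrast (t, df, p) against the reference plus Cohen's d. The primary d
#' is computed from raw (covariate-unadjusted) group means and the pooled
#' raw SD of the two groups, signed so that a deficit relative to the
#' reference is positive; an age-adjusted d (adjusted mean difference over
#' the same pooled SD) is also reported.
#'
#' @param outcome numeric outcome vector.
#' @param group factor (or character) of group membership.
#' @param age optional numeric covariate.
#' @param ref reference level (default `"CN"`, falling back to the first
#'   level present).
#' @return object of class `group_model_result`.
#' @export
group_model <- function(outcome, group, age = NULL, ref = "CN") {
  group <- factor(group)
  if (!ref %in% levels(group)) {
    if (identical(ref, "CN")) {
      stop("reference group 'CN' is missing")
    }
    stop("reference group '", ref, "' is missing")
  }
  keep <- !is.na(outcome) & !is.na(group)
  if (!is.null(age)) keep <- keep & !is.na(age)
  outcome <- outcome[keep]
  group <- droplevels(group[keep])
  if (!is.null(age)) age <- age[keep]
  if (any(table(group) < 2)) stop("every represented group needs n >= 2")
  group <- stats::relevel(group, ref = ref)
  dat <- data.frame(outcome = outcome, group = group)
  if (is.null(age)) {
    full <- stats::lm(outcome ~ group, data = dat)
    red <- stats::lm(outcome ~ 1, data = dat)
  } else {
    dat$age <- age
    full <- stats::lm(outcome ~ group + age, data = dat)
    red <- stats::lm(outcome ~ age, data = dat)
  }
  sm <- summary(full)
  fs <- sm$fstatistic
  overall <- list(F = unname(fs[1]), df = unname(fs[2:3]),
                  p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  av <- stats::anova(red, full)
  group_F <- list(F = av$F[2], df = c(av$Df[2], av$Res.Df[2]),
                  p = av$`Pr(>F)`[2])
  co <- sm$coefficients
  rdf <- full$df.residual
  contrasts <- list()
  for (g in levels(group)[-1]) {
    rn <- paste0("group", g)
    tval <- co[rn, "t value"]
    x_ref <- outcome[group == ref]
    x_g <- outcome[group == g]
    sp <- sqrt(((length(x_ref) - 1) * stats::var(x_ref) +
                (length(x_g) - 1) * stats::var(x_g)) /
               (length(x_ref) + length(x_g) - 2))
    contrasts[[g]] <- list(
      t = tval, df = rdf, p = co[rn, "Pr(>|t|)"],
      cohens_d = if (sp > 0) (mean(x_ref) - mean(x_g)) / sp else 0,
      cohens_d_adjusted = if (sp > 0) -co[rn, "Estimate"] / sp else 0)
  }
  structure(list(overall_F = overall, group_F = group_F,
                 contrasts = contrasts, n_used = length(outcome),
                 ref = ref, fit = full),
            class = "group_model_result")
}

#' @export
print.group_model_result <- function(x, ...) {
  cat(sprintf("<group_model> n = %d, ref = %s\n", x$n_used, x$ref))
  cat(sprintf("  overall F(%d,%d) = %.2f, p = %.3g\n",
              x$overall_F$df[1], x$overall_F$df[2], x$overall_F$F,
              x$overall_F$p))
  cat(sprintf("  group   F(%d,%d) = %.2f, p = %.3g\n",
              x$group_F$df[1], x$group_F$df[2], x$group_F$F, x$group_F$p))
  for (g in names(x$contrasts)) {
    ct <- x$contrasts[[g]]
    cat(sprintf("  %s vs %s: t(%d) = %.2f, p = %.3g, d = %.2f\n",
                g, x$ref, ct$df, ct$t, ct$p, ct$cohens_d))
  }
  invisible(x)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the OLS residuals of `x` and `y`, each
#' regressed on an intercept plus the covariates. With no covariates this
#' reduces to the plain Pearson correlation. The p value uses
#' `t = r sqrt(df / (1 - r^2))` with `df = n - k - 2` (k covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix / data frame of covariates.
#' @return list with `r`, `df`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    cm <- cbind(x, y)
  } else {
    covariates <- as.matrix(covariates)
    cm <- cbind(x, y, covariates)
  }
  keep <- stats::complete.cases(cm)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n <= k + 2) stop("need n > k + 2 observations")
  if (k > 0) {
    z <- cbind(1, covariates[keep, , drop = FALSE])
    x <- stats::lm.fit(z, x)$residuals
    y <- stats::lm.fit(z, y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Hierarchical stepwise regression with forced covariates
#'
#' The forced covariates (e.g. age and education) are always retained; the
#' candidate biomarkers are then entered one at a time, at each step adding
#' the candidate with the smallest partial-F p value provided it is below
#' `p_enter` (default 0.05), until none qualifies. Standardized
#' coefficients are computed by refitting the final model on z-scored
#' variables. Constant candidates are excluded with a warning.
#'
#' @param outcome numeric outcome.
#' @param forced data frame / matrix of forced covariates.
#' @param candidates data frame / matrix of candidate predictors (named).
#' @param p_enter entry threshold on the partial-F p value.
#' @return object of class `stepwise_result`: `forced` (coefficients),
#'   `entered` (ordered data frame of predictor, standardized beta, entry
#'   p), `final_F`, `final_df`, `n_used`.
#' @export
stepwise_hierarchical <- function(outcome, forced, candidates,
                                  p_enter = 0.05) {
  forced <- as.data.frame(forced)
  candidates <- as.data.frame(candidates)
  cc <- stats::complete.cases(cbind(outcome, forced, candidates))
  outcome <- outcome[cc]
  forced <- forced[cc, , drop = FALSE]
  candidates <- candidates[cc, , drop = FALSE]
  const <- vapply(candidates, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    warning("excluding constant candidate(s): ",
            paste(names(candidates)[const], collapse = ", "))
    candidates <- candidates[, !const, drop = FALSE]
  }
  dat <- cbind(data.frame(.y = outcome), forced, candidates)
  forced_terms <- names(forced)
  remaining <- names(candidates)
  entered <- character()
  entry_p <- numeric()
  fml <- function(terms) {
    stats::as.formula(paste(".y ~", paste(c("1", terms), collapse = " + ")))
  }
  fit0 <- stats::lm(fml(forced_terms), data = dat)
  while (length(remaining) > 0) {
    ps <- vapply(remaining, function(cand) {
      fit1 <- stats::lm(fml(c(forced_terms, entered, cand)), data = dat)
      av <- stats::anova(fit0, fit1)
      av$`Pr(>F)`[2]
    }, numeric(1))
    best <- which.min(ps)
    if (ps[best] >= p_enter) break
    entered <- c(entered, remaining[best])
    entry_p <- c(entry_p, ps[best])
    remaining <- remaining[-best]
    fit0 <- stats::lm(fml(c(forced_terms, entered)), data = dat)
  }
  final <- fit0
  sm <- summary(final)
  fs <- sm$fstatistic
  zdat <- as.data.frame(lapply(dat, function(v) {
    if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
  }))
  zfit <- stats::lm(fml(c(forced_terms, entered)), data = zdat)
  zco <- stats::coef(zfit)
  entered_df <- data.frame(predictor = entered,
                           beta = if (length(entered))
                             unname(zco[entered]) else numeric(),
                           p = entry_p, stringsAsFactors = FALSE)
  structure(list(forced = stats::coef(final)[forced_terms],
                 forced_beta = zco[forced_terms],
                 entered = entered_df,
                 final_F = unname(fs[1]), final_df = unname(fs[2:3]),
                 final_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
                 n_used = length(outcome), fit = final),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise> n = %d; final F(%d,%d) = %.2f, p = %.3g\n",
              x$n_used, x$final_df[1], x$final_df[2], x$final_F, x$final_p))
  if (nrow(x$entered) == 0) {
    cat("  no candidate entered\n")
  } else {
    for (i in seq_len(nrow(x$entered))) {
      cat(sprintf("  step %d: %s (beta = %.2f, entry p = %.3g)\n", i,
                  x$entered$predictor[i], x$entered$beta[i], x$entered$p[i]))
    }
  }
  invisible(x)
}
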