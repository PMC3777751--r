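# Group statistics battery.

test_that("summary t-test matches a raw-data pooled t on a constructed sample", {
  # build samples with exactly the requested means and SDs
  make_sample <- function(m, s, n) {
    x <- stats::rnorm(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  set.seed(14)
  x1 <- make_sample(73.0, 7.0, 44)
  x2 <- make_sample(68.7, 7.2, 31)
  tt <- ttest_from_summary(73.0, 7.0, 44, 68.7, 7.2, 31)
  raw <- stats::t.test(x1, x2, var.equal = TRUE)
  expect_equal(tt$t, unname(raw$statistic), tolerance = 1e-8)
  expect_equal(tt$df, unname(raw$parameter))
  expect_equal(tt$p, raw$p.value, tolerance = 1e-8)
})

test_that("summary t-test is antisymmetric and null at equality", {
  a <- ttest_from_summary(10, 2, 20, 12, 3, 25)
  b <- ttest_from_summary(12, 3, 25, 10, 2, 20)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  eq <- ttest_from_summary(5, 1, 10, 5, 1, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(ttest_from_summary(5, 1, 1, 5, 1, 12), "n >= 2")
  expect_error(ttest_from_summary(5, 0, 10, 5, 1, 12), "positive")
})

test_that("chi-square matches brute-force expected counts", {
  tab <- matrix(c(26, 18, 4, 11), 2, byrow = TRUE)
  res <- chi2_frequencies(tab)
  # independent expected-count computation
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  chi2 <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- rs[i] * cs[j] / n
    chi2 <- chi2 + (tab[i, j] - e)^2 / e
  }
  expect_equal(res$chi2, chi2, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_lt(res$p, 0.05)
  # perfectly proportional table gives zero
  prop <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)
  expect_equal(chi2_frequencies(prop)$chi2, 0, tolerance = 1e-12)
  expect_error(chi2_frequencies(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("single-dummy group model reproduces the pooled two-sample t", {
  set.seed(21)
  y <- c(stats::rnorm(20, 50, 8), stats::rnorm(15, 44, 8))
  g <- factor(rep(c("CN", "AD"), c(20, 15)), levels = c("CN", "AD"))
  gm <- group_model(y, g)
  tt <- stats::t.test(y[g == "CN"], y[g == "AD"], var.equal = TRUE)
  expect_equal(gm$overall_F$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(gm$contrasts$AD$t^2, unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(gm$contrasts$AD$p, tt$p.value, tolerance = 1e-8)
})

test_that("group model requires the reference group and balanced basics", {
  y <- stats::rnorm(30)
  g <- factor(rep(c("EMCI", "AD"), 15))
  expect_error(group_model(y, g), "CN")
  # constant outcome: age coefficient exactly zero
  y2 <- rep(5, 40)
  g2 <- factor(rep(c("CN", "AD"), 20))
  age <- stats::rnorm(40, 70, 5)
  gm <- suppressWarnings(group_model(y2, g2, age))
  expect_equal(unname(stats::coef(gm$fit)["age"]), 0, tolerance = 1e-12)
})

test_that("group model recovers a built-in one-SD AD deficit", {
  ds <- vapply(1:12, function(s) {
    cs <- cohort_spec(group_cbf_means = c(50, 50, 50, 42),
                      group_cbf_sds = rep(8, 4), cbf_meas_sd = 0, seed = s)
    co <- simulate_cohort(cs)
    gm <- group_model(co$meta_roi_cbf, co$group, co$age)
    expect_lt(gm$contrasts$AD$t, 0)
    gm$contrasts$AD$cohens_d
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1), 0.3)
})

test_that("group-F type-I error stays near the nominal level", {
  set.seed(1)
  grp <- factor(rep(c("CN", "EMCI", "LMCI", "AD"), c(44, 31, 30, 15)),
                levels = c("CN", "EMCI", "LMCI", "AD"))
  age <- stats::rnorm(120, 72, 7.5)
  rej <- mean(replicate(400, {
    y <- stats::rnorm(120)
    group_model(y, grp, age)$group_F$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("partial correlation reduces to Pearson and matches the matrix-inverse oracle", {
  set.seed(33)
  n <- 60
  x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n)
  z1 <- stats::rnorm(n); z2 <- 0.3 * x + stats::rnorm(n)
  expect_equal(partial_correlation(x, y)$r, stats::cor(x, y),
               tolerance = 1e-12)
  # inverse-correlation-matrix identity: r_xy.z = -P12 / sqrt(P11 P22)
  cm <- stats::cor(cbind(x, y, z1, z2))
  pm <- solve(cm)
  oracle <- -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
  pc <- partial_correlation(x, y, cbind(z1, z2))
  expect_equal(pc$r, oracle, tolerance = 1e-10)
  # symmetry in x and y
  expect_equal(partial_correlation(y, x, cbind(z1, z2))$r, pc$r,
               tolerance = 1e-12)
  # perfect residual association
  y2 <- x + 2 * z1 - z2
  expect_equal(partial_correlation(x, y2, cbind(z1, z2))$r, 1,
               tolerance = 1e-8)
  expect_error(partial_correlation(x[1:3], y[1:3], cbind(z1, z2)[1:3, ]),
               "need n")
})

test_that("stepwise agrees with exhaustive evaluation of the four candidate models", {
  brute_force <- function(y, forced, cand, p_enter = 0.05) {
    # enumerate the entry sequences allowed by the rule and pick the one
    # the procedure would follow
    dat <- cbind(data.frame(.y = y), forced, cand)
    fit <- function(terms) stats::lm(
      stats::as.formula(paste(".y ~", paste(c("1", terms), collapse = "+"))),
      data = dat)
    addp <- function(base_terms, cand_name) {
      stats::anova(fit(base_terms),
                   fit(c(base_terms, cand_name)))$`Pr(>F)`[2]
    }
    fterms <- names(forced)
    entered <- character()
    repeat {
      rem <- setdiff(names(cand), entered)
      if (!length(rem)) break
      ps <- vapply(rem, function(cn) addp(c(fterms, entered), cn),
                   numeric(1))
      if (min(ps) >= p_enter) break
      entered <- c(entered, rem[which.min(ps)])
    }
    entered
  }
  set.seed(44)
  n <- 90
  forced <- data.frame(age = stats::rnorm(n, 72, 7),
                       education = stats::rnorm(n, 16, 3))
  for (rep in 1:8) {
    b1 <- sample(c(0, 0.3, 0.8), 1); b2 <- sample(c(0, 0.4), 1)
    cand <- data.frame(cbf = stats::rnorm(n), hippo = stats::rnorm(n))
    y <- 0.05 * forced$age + b1 * cand$cbf + b2 * cand$hippo +
      stats::rnorm(n)
    sw <- stepwise_hierarchical(y, forced, cand)
    expect_identical(sw$entered$predictor, brute_force(y, forced, cand))
  }
})

test_that("stepwise respects the entry threshold and degenerate cases", {
  set.seed(55)
  n <- 100
  forced <- data.frame(age = stats::rnorm(n, 72, 7),
                       education = stats::rnorm(n, 16, 3))
  cand <- data.frame(cbf = stats::rnorm(n), hippo = stats::rnorm(n))
  y <- 2 + 0.6 * cand$cbf - 0.5 * cand$hippo + stats::rnorm(n)
  # strong independent effects: both enter with recovered signs
  sw <- stepwise_hierarchical(y, forced, cand)
  expect_setequal(sw$entered$predictor, c("cbf", "hippo"))
  expect_gt(sw$entered$beta[sw$entered$predictor == "cbf"], 0)
  expect_lt(sw$entered$beta[sw$entered$predictor == "hippo"], 0)
  # p_enter = 1 admits everything and equals the full OLS
  sw_all <- stepwise_hierarchical(y, forced, cand, p_enter = 1)
  full <- stats::lm(y ~ age + education + cbf + hippo,
                    data = cbind(forced, cand))
  expect_equal(sort(sw_all$entered$predictor), c("cbf", "hippo"))
  expect_equal(unname(stats::coef(sw_all$fit)[c("cbf", "hippo")]),
               unname(stats::coef(full)[c("cbf", "hippo")]),
               tolerance = 1e-10)
  # pure-noise candidate stays out at the null rate: just check a null run
  y0 <- stats::rnorm(n)
  sw0 <- stepwise_hierarchical(y0, forced,
                               data.frame(noisevar = stats::rnorm(n)),
                               p_enter = 1e-6)
  expect_equal(nrow(sw0$entered), 0L)
  # constant candidate excluded with a warning
  expect_warning(
    stepwise_hierarchical(y, forced,
                          data.frame(cbf = cand$cbf, flat = rep(1, n))),
    "constant")
})
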