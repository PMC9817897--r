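test_that("fit_hetero_groups reproduces the Welch contrast by hand", {
  d <- data.frame(
    g = rep(c("a", "b"), each = 5),
    v = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15)
  )
  fit <- fit_hetero_groups(d, "g", "v", reference = "a")
  ct <- fit$contrasts
  expect_equal(ct$estimate, -10)
  expect_equal(ct$se, 1) # sqrt(2.5 * (1/5 + 1/5))
  expect_equal(ct$t, -10)
  expect_equal(ct$df, 8)
  expect_equal(ct$type, "vs_reference")

  # identical groups: estimate 0, p = 1
  d2 <- data.frame(g = rep(c("a", "b"), each = 4), v = rep(c(1, 2, 3, 4), 2))
  ct2 <- fit_hetero_groups(d2, "g", "v")$contrasts
  expect_equal(ct2$estimate, 0)
  expect_equal(ct2$p_raw, 1)

  expect_error(
    fit_hetero_groups(
      data.frame(g = c("a", "a", "b"), v = 1:3), "g", "v"
    ),
    "insufficient data.*b"
  )
})

test_that("Welch contrasts agree with t.test across random draws", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(8, 0, 1)
    y <- rnorm(12, 1, 4)
    d <- data.frame(g = rep(c("x", "y"), c(8, 12)), v = c(x, y))
    ct <- fit_hetero_groups(d, "g", "v")$contrasts
    tt <- t.test(x, y)
    expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(ct$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(ct$p_raw, tt$p.value, tolerance = 1e-12)
  }
})

test_that("Welch converges to the pooled t when variances are equal", {
  set.seed(77)
  x <- rnorm(40)
  y <- rnorm(40, 0.5)
  d <- data.frame(g = rep(c("x", "y"), each = 40), v = c(x, y))
  ct <- fit_hetero_groups(d, "g", "v")$contrasts
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(ct$t, unname(pooled$statistic), tolerance = 0.02)
  expect_equal(ct$p_raw, pooled$p.value, tolerance = 0.02)
})

test_that("holm_adjust implements the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  # never decreases and matches the reference implementation
  set.seed(11)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fit_blocked_ols recovers known effects and balanced emmeans", {
  te <- c(ctrl = 0, inhbb = 0.4, inhbc = -0.2)
  de <- c(d1 = 0.15, d2 = -0.05, d3 = 0.1)
  tab <- generate_assay_table(te, de, resid_sd = 0, n_rep = 3, seed = 1)
  # the zero-noise fixture triggers lm's perfect-fit warning by construction
  fit <- suppressWarnings(fit_blocked_ols(tab))
  # noise-free: fitted values are exact
  expect_lt(max(abs(fitted(fit$model) - tab$value)), 1e-10)
  # balanced design: emmeans equal raw treatment means despite date effects
  raw <- tapply(tab$value, tab$treatment, mean)
  expect_equal(fit$emmeans$estimate, as.numeric(raw[fit$emmeans$treatment]),
    tolerance = 1e-8
  )
  expect_true(all(fit$emmeans$ci_low <= fit$emmeans$ci_high))

  # residuals orthogonal to every design column
  noisy <- generate_assay_table(te, de, resid_sd = 0.1, n_rep = 4, seed = 2)
  nf <- fit_blocked_ols(noisy)
  mm <- model.matrix(nf$model)
  expect_lt(max(abs(crossprod(mm, residuals(nf$model)))), 1e-8)

  # single date level: blocking is vacuous
  one_date <- generate_assay_table(te, c(d1 = 0.3), 0.05, 3, seed = 3)
  f1 <- fit_blocked_ols(one_date)
  raw1 <- tapply(one_date$value, one_date$treatment, mean)
  expect_equal(f1$emmeans$estimate, as.numeric(raw1[f1$emmeans$treatment]),
    tolerance = 1e-10
  )

  # aliased predictors are reported
  dup <- tab
  dup$date <- dup$treatment
  expect_error(fit_blocked_ols(dup), "collinear")
})

test_that("fit_nb_glm matches glm.nb and the Poisson limit", {
  x <- cbind(1, rep(0:1, each = 150))
  y <- generate_nb_counts(x, c(log(40), 0.5), theta = 2.5, seed = 19)
  fit <- fit_nb_glm(y, x)
  expect_true(fit$converged)
  ref <- MASS::glm.nb(y ~ x[, 2])
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-4)
  expect_equal(
    unname(fit$se_beta),
    unname(summary(ref)$coefficients[, 2]),
    tolerance = 1e-3
  )

  # intercept-only MLE is the sample mean
  y0 <- generate_nb_counts(matrix(1, 200), log(30), 1.5, seed = 23)
  f0 <- fit_nb_glm(y0, matrix(1, 200))
  expect_equal(unname(exp(f0$beta)), mean(y0), tolerance = 1e-8)

  # near-Poisson data: beta matches a Poisson fit closely
  yp <- generate_nb_counts(x, c(log(20), 0.3), theta = 1e9, seed = 29)
  fp <- fit_nb_glm(yp, x)
  pois <- glm(yp ~ x[, 2], family = poisson())
  expect_equal(unname(fp$beta), unname(coef(pois)), tolerance = 1e-4)

  expect_error(fit_nb_glm(c(1.5, 2, 3), matrix(1, 3)), "non-negative integers")
  expect_error(fit_nb_glm(c(1, 2, 3), cbind(1, c(2, 2, 2))), "full column rank")
})

test_that("loading-control normalisation divides lane by lane", {
  expect_equal(normalize_to_loading_control(c(10, 20), c(2, 4)), c(5, 5))
  expect_equal(normalize_to_loading_control(1:3, rep(1, 3)), 1:3)
  expect_equal(normalize_to_loading_control(c(3, 3), c(3, 3)), c(1, 1))
  expect_error(
    normalize_to_loading_control(c(1, 2), c(1, 0)),
    "lane\\(s\\): 2"
  )
  expect_error(normalize_to_loading_control(1:3, 1:2), "equal length")
})

test_that("fold_changes tests the per-date ratios against 1", {
  same <- fold_changes(c(d1 = 2, d2 = 3), c(d1 = 2, d2 = 3))
  expect_equal(unname(same$fold_changes), c(1, 1))
  expect_equal(same$p, 1)

  up <- fold_changes(c(d1 = 2, d2 = 4, d3 = 6), c(d1 = 1, d2 = 2, d3 = 3))
  expect_equal(unname(up$fold_changes), c(2, 2, 2))
  expect_equal(up$p, 0) # degenerate: identical fold changes != 1

  set.seed(41)
  tr <- exp(rnorm(10, 0.5, 0.2))
  ctl <- rep(1, 10)
  names(tr) <- names(ctl) <- paste0("d", 1:10)
  fc <- fold_changes(tr, ctl)
  tt <- t.test(tr, mu = 1)
  expect_equal(fc$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(fc$p, tt$p.value, tolerance = 1e-12)

  expect_error(
    fold_changes(c(d1 = 1), c(d2 = 1)),
    "pairing error"
  )
})

test_that("correlation utilities match hand computations", {
  lin <- pearson_corr(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$r_squared, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)

  pc <- pearson_corr(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pc$r, 0.8)
  expect_equal(pc$r_squared, 0.64)
  ref <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pc$p, ref$p.value, tolerance = 1e-12)

  sp <- spearman_corr(c(1, 2, 3), c(2, 1, 3))
  expect_equal(sp$rho, 0.5)
  expect_equal(spearman_corr(1:8, 8:1)$rho, -1)

  # invariant under strictly monotone transforms
  set.seed(2)
  x <- rnorm(30)
  y <- rnorm(30)
  base <- spearman_corr(x, y)$rho
  expect_equal(spearman_corr(exp(x), y)$rho, base)
  expect_equal(spearman_corr(x, y^3)$rho, base)

  expect_error(pearson_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})
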