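test_that("sandwich identities: HC1 rescales HC0; HC2 = HC1 under balanced leverage", {
  set.seed(12)
  n <- 40
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, 0, abs(x) + 0.3)
  fit <- lm(y ~ x)
  p <- 2
  v0 <- robust_covariance(fit, "HC0")
  v1 <- robust_covariance(fit, "HC1")
  expect_equal(v1, v0 * n / (n - p), tolerance = 1e-12)

  # balanced design: identical leverage for every observation, h_i = p/n
  xb <- rep(c(-1, 1), each = 10)
  yb <- rnorm(20)
  fitb <- lm(yb ~ xb)
  expect_equal(unname(range(hatvalues(fitb))), rep(2 / 20, 2), tolerance = 1e-12)
  expect_equal(robust_covariance(fitb, "HC2"), robust_covariance(fitb, "HC1"),
               tolerance = 1e-12)
})

test_that("the sandwich matches longhand arithmetic on six observations", {
  x <- c(0, 1, 2, 3, 4, 5)
  y <- c(0.2, 1.1, 1.9, 3.4, 3.7, 5.3)
  fit <- lm(y ~ x)
  X <- cbind(1, x)
  e <- residuals(fit)
  bread <- solve(t(X) %*% X)
  h <- diag(X %*% bread %*% t(X))
  for (type in c("HC0", "HC1", "HC2", "HC3")) {
    w <- switch(type,
      HC0 = rep(1, 6),
      HC1 = rep(6 / (6 - 2), 6),
      HC2 = 1 / (1 - h),
      HC3 = 1 / (1 - h)^2
    )
    v_hand <- bread %*% t(X) %*% diag(w * e^2) %*% X %*% bread
    expect_equal(unname(robust_covariance(fit, type)), unname(v_hand),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("a leverage-one observation is rejected by name under HC2/HC3", {
  x <- c(0, 0, 0, 5)  # the fourth point determines its own fit
  y <- c(1, 2, 1.5, 9)
  fit <- lm(y ~ x)
  expect_error(robust_covariance(fit, "HC2"), "observation")
  expect_true(is.matrix(suppressWarnings(robust_covariance(fit, "HC0"))))
})

test_that("an exactly determined dv gives step-1 fit of 1 and zero increments", {
  set.seed(13)
  df <- tibble::tibble(a = rnorm(60), b = rnorm(60), z = rnorm(60))
  df$y <- 2 * df$a - df$b + 1
  spec <- step_spec(list(c("a", "b"), "z"), dv = "y", robust_type = "HC0")
  # a perfect fit makes summary()/sandwich warn about reliability; intended here
  fit <- suppressWarnings(fit_hierarchical(df, spec))
  g <- glance(fit)
  expect_equal(g$adj_r_squared[[1]], 1, tolerance = 1e-10)
  expect_equal(g$delta_r2[[2]], 0, tolerance = 1e-10)
})

test_that("adding pure noise gives small non-negative increments", {
  set.seed(14)
  n <- 400
  df <- tibble::tibble(a = rnorm(n), noise = rnorm(n))
  df$y <- df$a + rnorm(n)
  fit <- fit_hierarchical(df, step_spec(list("a", "noise"), dv = "y"))
  g <- glance(fit)
  expect_gte(g$delta_r2[[2]], 0)
  expect_lt(g$delta_r2[[2]], 0.03)
  # unadjusted R-squared is monotone across steps
  expect_true(all(diff(g$r_squared) >= -1e-12))
})

test_that("mean-centring changes only the intercept", {
  set.seed(15)
  n <- 120
  df <- tibble::tibble(a = rnorm(n, 5), b = rnorm(n, -2), s = rnorm(n, 4))
  df$y <- 0.3 * df$a - 0.2 * df$b + 0.1 * df$s + rnorm(n)
  spec_c <- step_spec(list(c("a", "b"), "s"), dv = "y", center_predictors = TRUE)
  spec_u <- step_spec(list(c("a", "b"), "s"), dv = "y", center_predictors = FALSE)
  fc <- fit_hierarchical(df, spec_c)
  fu <- fit_hierarchical(df, spec_u)
  tc <- tidy(fc)
  tu <- tidy(fu)
  slopes_c <- tc[tc$term != "(Intercept)", ]
  slopes_u <- tu[tu$term != "(Intercept)", ]
  expect_equal(slopes_c$estimate, slopes_u$estimate, tolerance = 1e-10)
  expect_equal(slopes_c$se_robust, slopes_u$se_robust, tolerance = 1e-10)
  expect_equal(glance(fc)$delta_r2, glance(fu)$delta_r2, tolerance = 1e-12)
  int_c <- tc$estimate[tc$term == "(Intercept)" & tc$step == 2]
  int_u <- tu$estimate[tu$term == "(Intercept)" & tu$step == 2]
  expect_false(isTRUE(all.equal(int_c, int_u)))
})

test_that("robust SEs approach classical SEs under homoskedastic errors", {
  set.seed(16)
  n <- 5000
  df <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  df$y <- 0.5 * df$a - 0.3 * df$b + rnorm(n)
  fit <- fit_hierarchical(df, step_spec(list(c("a", "b")), dv = "y"))
  lm_fit <- lm(y ~ a + b, data = dplyr::mutate(df, a = a - mean(a), b = b - mean(b)))
  se_classical <- sqrt(diag(vcov(lm_fit)))
  se_robust <- tidy(fit)$se_robust
  expect_lt(max(abs(se_robust / se_classical - 1)), 0.05)
})

test_that("listwise deletion is counted and missing columns are named", {
  df <- tibble::tibble(a = c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10),
                       y = c(1.4, NA, 2.8, 4.1, 5.2, 5.8, 7.1, 8.4, 8.9, 10.2))
  fit <- fit_hierarchical(df, step_spec(list("a"), dv = "y"))
  expect_equal(fit$n_dropped, 2L)
  expect_equal(fit$n, 8L)
  expect_error(fit_hierarchical(df, step_spec(list("missing_col"), dv = "y")),
               "missing_col")
})

test_that("step_spec validates blocks and dv", {
  expect_error(step_spec(list(c("a", "b"), "a"), dv = "y"), "disjoint")
  expect_error(step_spec(list("a"), dv = "a"), "dv")
})

test_that("zero-order correlations: exact cases and degenerate flagging", {
  set.seed(17)
  df <- tibble::tibble(x = rnorm(30))
  df$minus <- -df$x
  df$twice <- 2 * df$x
  df$flat <- 1
  ct <- zero_order_correlations(df, c("x", "minus", "twice", "flat"))
  mat <- attr(ct, "matrix")
  expect_equal(diag(mat), c(x = 1, minus = 1, twice = 1, flat = 1))
  expect_equal(mat["x", "minus"], -1)
  expect_equal(mat["x", "twice"], 1)
  expect_true(all(ct$degenerate[ct$var1 == "flat" | ct$var2 == "flat"]))
  expect_false(anyNA(ct$r[!ct$degenerate]))
  expect_equal(mat, t(mat))
})

test_that("correlation estimates track a planted bivariate correlation", {
  set.seed(18)
  n <- 2829
  rho <- 0.45
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  ct <- zero_order_correlations(tibble::tibble(x = x, y = y))
  # Fisher-z tolerance at this n is about +/- .03
  expect_lt(abs(ct$r[[1]] - rho), 0.03)
  expect_lt(ct$p_value[[1]], 0.001)
})

test_that("category splits partition the table", {
  df <- tibble::tibble(v = 1:10,
                       cat = rep(c("concrete", "abstract"), c(6, 4)))
  parts <- split_by_category(df, "cat")
  expect_equal(vapply(parts, nrow, integer(1)),
               c(concrete = 6L, abstract = 4L))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(df))
  expect_warning(split_by_category(df, "cat", values = c("concrete", "gone")),
                 "gone")
  expect_error(split_by_category(df, "nope"), "nope")
})
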