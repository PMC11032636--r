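test_that("fit_ols matches hand arithmetic on a five-point problem", {
  # bivariate fit computed longhand from the normal equations
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(0, 1, 0, 1, 1))
  y <- c(1.0, 2.1, 2.9, 4.2, 4.8)
  fit <- fit_ols(x, y)
  xm <- cbind(1, x)
  beta_hand <- unname(drop(solve(t(xm) %*% xm, t(xm) %*% y)))
  expect_equal(fit$intercept, beta_hand[[1]])
  expect_equal(unname(fit$coefficients), beta_hand[2:3])
  expect_equal(fit$rss, sum((y - xm %*% beta_hand)^2))

  # perfect linear response: zero residuals, adjusted R^2 of 1
  y2 <- drop(xm %*% c(0.5, 2, -1))
  fit2 <- fit_ols(x, y2)
  expect_equal(fit2$residuals, rep(0, 5), tolerance = 1e-12)
  expect_equal(fit2$adj_r_squared, 1)

  # response orthogonal to the centred design: zero slopes
  set.seed(4)
  x3 <- matrix(rnorm(40), 20, 2)
  y3 <- rnorm(20)
  y3 <- y3 - stats::lm.fit(cbind(1, x3), y3)$fitted.values + mean(y3)
  fit3 <- fit_ols(x3, y3)
  expect_equal(unname(fit3$coefficients), c(0, 0), tolerance = 1e-10)
  expect_lte(fit3$adj_r_squared, 0)

  expect_error(fit_ols(matrix(rnorm(6), 2, 3), rnorm(2)), "n > p")
})

test_that("the full-model subset has Cp exactly equal to p", {
  set.seed(5)
  pb <- random_problem(n = 80, k = 5, sigma = 2)
  # force every variable to matter so the full model is selected
  y <- drop(pb$x %*% runif(5, 1, 2)) + rnorm(80, 0, 0.3)
  m <- best_subset_cp(pb$x, y)
  if (length(m$selected) == 5L) {
    expect_equal(m$cp, 6, tolerance = 1e-8)
  }
  # the identity holds by construction for any full fit:
  # RSS_full / sigma2_full = n - p_full
  full <- fit_ols(pb$x, y)
  cp_full <- full$rss / m$sigma2_full + 2 * (5 + 1) - 80
  expect_equal(cp_full, 6, tolerance = 1e-8)
})

test_that("branch-and-bound equals exhaustive enumeration on 8-feature problems", {
  set.seed(6)
  for (rep in 1:10) {
    pb <- random_problem(n = 50, k = 8, sigma = 1.5)
    a <- best_subset_cp(pb$x, pb$y, method = "branch_and_bound")
    b <- best_subset_cp(pb$x, pb$y, method = "exhaustive")
    oracle <- oracle_best_subset(pb$x, pb$y)
    expect_equal(a$selected, b$selected)
    expect_equal(a$selected, oracle$selected)
    expect_equal(a$cp, oracle$cp, tolerance = 1e-6)
  }
})

test_that("strong planted signal is recovered with accurate coefficients", {
  set.seed(7)
  x <- matrix(rnorm(500 * 8), 500, 8)
  colnames(x) <- paste0("x", 1:8)
  y <- 2 * x[, 1] - x[, 2] + rnorm(500, 0, 0.01)
  m <- best_subset_cp(x, y)
  expect_true(all(c("x1", "x2") %in% m$selected))
  expect_equal(unname(m$coefficients["x1"]), 2, tolerance = 0.05)
  expect_equal(unname(m$coefficients["x2"]), -1, tolerance = 0.05)
})

test_that("RSS is monotone non-increasing over nested subsets", {
  set.seed(8)
  pb <- random_problem(n = 100, k = 6, sigma = 1)
  ord <- sample(6)
  rss_prev <- Inf
  for (j in seq_along(ord)) {
    fit <- fit_ols(pb$x[, ord[seq_len(j)], drop = FALSE], pb$y)
    expect_lte(fit$rss, rss_prev + 1e-10)
    rss_prev <- fit$rss
  }
})

test_that("degenerate inputs are rejected with directed messages", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  colnames(x) <- c("a", "b", "c")
  y_exact <- drop(x %*% c(1, 2, 3))
  expect_error(best_subset_cp(x, y_exact), "noise")
  x_dep <- cbind(x, d = x[, 1] + x[, 2])
  expect_error(best_subset_cp(x_dep, rnorm(20)), "find_linear_combos")
})

test_that("typicality scores are an exact z-transform with stored constants", {
  set.seed(10)
  cfg <- synthetic_config(n_words = 250, seed = 61)
  lex <- generate_size_ratings(generate_lexicon(cfg), cfg)
  fm <- build_feature_matrix(lex)
  pr <- find_linear_combos(fm[, form_feature_names()])
  x <- prune_features(fm, pr)
  x$word <- NULL
  m <- best_subset_cp(x, lex$rating_mean, max_features = 10)
  ty <- compute_typicality(m, fm)

  expect_equal(mean(ty$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(ty$z), 1, tolerance = 1e-10)
  expect_equal(order(ty$z), order(ty$fitted))

  # scoring new words reuses the stored standardization constants
  sub <- compute_typicality(m, fm[1:10, ])
  expect_equal(sub$z, ty$z[1:10])
})

test_that("one extra syllable moves the fitted size by the planted slope", {
  coefs <- size_model_defaults()
  m <- subset_model(intercept = coefs[["(Intercept)"]], coefficients = coefs[-1])
  base <- extract_features(c("B", "AH1", "G"), n_letters = 3)
  # two words identical except for one extra syllable
  f1 <- tibble::as_tibble(as.list(base))
  f2 <- f1
  f2$n_syllables <- f1$n_syllables + 1
  scores <- compute_typicality(m, dplyr::bind_rows(f1, f2, f1))
  expect_equal(scores$fitted[[2]] - scores$fitted[[1]], 0.361)
})

test_that("degenerate constant fitted values are rejected", {
  coefs <- c(n_high = 0.5)
  m <- subset_model(intercept = 3, coefficients = coefs)
  feats <- tibble::tibble(n_high = rep(2, 4))
  expect_error(compute_typicality(m, feats), "zero spread")
})

test_that("typicality z-scores are invariant to affine rescaling of the response", {
  set.seed(11)
  cfg <- synthetic_config(n_words = 200, seed = 71)
  lex <- generate_size_ratings(generate_lexicon(cfg), cfg)
  fm <- build_feature_matrix(lex)
  pr <- find_linear_combos(fm[, form_feature_names()])
  x <- prune_features(fm, pr)
  x$word <- NULL
  m1 <- best_subset_cp(x, lex$rating_mean, max_features = 8)
  m2 <- best_subset_cp(x, 10 + 4 * lex$rating_mean, max_features = 8)
  expect_equal(m2$selected, m1$selected)
  t1 <- compute_typicality(m1, fm)
  t2 <- compute_typicality(m2, fm)
  # fitted values transform by the same affine map; z-scores are unchanged
  expect_equal(t2$fitted, 10 + 4 * t1$fitted, tolerance = 1e-8)
  expect_equal(t2$z, t1$z, tolerance = 1e-8)
})

test_that("model JSON serialization round-trips scoring bit for bit", {
  cfg <- synthetic_config(n_words = 150, seed = 81)
  lex <- generate_size_ratings(generate_lexicon(cfg), cfg)
  fm <- build_feature_matrix(lex)
  pr <- find_linear_combos(fm[, form_feature_names()])
  x <- prune_features(fm, pr)
  x$word <- NULL
  m <- best_subset_cp(x, lex$rating_mean, max_features = 6)
  path <- tempfile(fileext = ".json")
  write_subset_model(m, path)
  m2 <- read_subset_model(path)
  expect_equal(compute_typicality(m2, fm)$z, compute_typicality(m, fm)$z,
               tolerance = 1e-12)
  # writing the restored model again reproduces the file byte for byte
  path2 <- tempfile(fileext = ".json")
  write_subset_model(m2, path2)
  expect_identical(readLines(path2), readLines(path))

  t1 <- tidy(m)
  expect_equal(t1$term[[1]], "(Intercept)")
  g1 <- glance(m)
  expect_equal(g1$n_selected, length(m$selected))
})
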