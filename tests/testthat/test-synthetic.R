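test_that("generation is deterministic under the seed and validates config", {
  cfg <- synthetic_config(n_words = 150, seed = 5)
  a <- generate_lexicon(cfg)
  b <- generate_lexicon(cfg)
  expect_identical(a, b)
  other <- generate_lexicon(synthetic_config(n_words = 150, seed = 6))
  expect_false(identical(a$orthography, other$orthography))

  expect_error(synthetic_config(n_words = 0), "n_words")
  expect_error(synthetic_config(n_raters = 1), "n_raters")
  expect_error(synthetic_config(syllable_dist = c(`1` = 0.5, `2` = 0.4)),
               "sum to 1")
  expect_error(synthetic_config(onset_inventory = character()), "non-empty")
})

test_that("orthographies are unique and pronunciations are legal ARPAbet", {
  cfg <- synthetic_config(n_words = 300, seed = 15)
  lex <- generate_lexicon(cfg)
  expect_equal(anyDuplicated(lex$orthography), 0L)
  inv <- arpabet_inventory()
  for (ph in lex$phonemes[1:50]) {
    base <- sub("[012]$", "", ph)
    expect_true(all(base %in% inv))
  }
  # at least one vowel everywhere (syllable counts are defined)
  fm <- build_feature_matrix(lex)
  expect_true(all(fm$n_syllables >= 1))
})

test_that("syllable counts follow the configured distribution within 99% bands", {
  cfg <- synthetic_config(n_words = 2924, seed = 25)
  lex <- generate_lexicon(cfg)
  fm <- build_feature_matrix(lex)
  counts <- table(factor(fm$n_syllables, levels = 1:5))
  probs <- cfg$syllable_dist
  for (k in 1:5) {
    p <- probs[[as.character(k)]]
    lo <- qbinom(0.005, 2924, p)
    hi <- qbinom(0.995, 2924, p)
    expect_gte(counts[[k]], lo)
    expect_lte(counts[[k]], hi)
  }
})

test_that("every phonetic feature category is reachable in generated data", {
  cfg <- synthetic_config(n_words = 2000, seed = 35)
  fm <- build_feature_matrix(generate_lexicon(cfg))
  count_cols <- grep("^n_", form_feature_names(), value = TRUE)
  for (col in count_cols) {
    expect_gt(sum(fm[[col]]), 0)
  }
  # all four stress codes occur
  for (col in c("stress_initial", "stress_final", "stress_medial",
                "stress_multiple")) {
    expect_gt(sum(fm[[col]]), 0)
  }
})

test_that("noise-free ratings collapse to the clamped rounded linear predictor", {
  cfg <- synthetic_config(n_words = 100, seed = 45, sd_word = 0, sd_rater = 0)
  lex <- generate_size_ratings(generate_lexicon(cfg), cfg)
  fm <- build_feature_matrix(lex)
  coefs <- cfg$coefficients
  eta <- drop(as.matrix(fm[, names(coefs[-1])]) %*% coefs[-1]) + coefs[[1]]
  expect_equal(lex$true_size, eta)
  expect_equal(lex$rating_sd, rep(0, 100))
  expect_equal(lex$rating_mean, pmin(pmax(round(eta), 1), 7))
})

test_that("heavy rater disagreement produces words the SD filter removes", {
  cfg <- synthetic_config(n_words = 400, seed = 55, sd_rater = 1.3,
                          sd_rater_spread = 0.6)
  lex <- generate_size_ratings(generate_lexicon(cfg), cfg)
  expect_gt(sum(lex$rating_sd > 1.5), 0)
  norms <- tibble::tibble(word = lex$orthography, size_mean = lex$rating_mean,
                          size_sd = lex$rating_sd, pos = lex$pos,
                          homograph_alternate = lex$homograph_alternate)
  kept <- apply_exclusions(norms)
  expect_lt(nrow(kept), nrow(norms))
  expect_true(all(kept$size_sd <= 1.5))
})

test_that("rating means are nearly unbiased for moderate latent sizes", {
  # clamping bias bound: rater SD <= 1 and true scores well inside the scale
  set.seed(65)
  true_size <- seq(2.5, 5.5, length.out = 40)
  n_raters <- 20000  # large so Monte-Carlo error (~0.007) is negligible
  ratings <- matrix(rnorm(40 * n_raters, mean = true_size, sd = 1), nrow = 40)
  ratings <- pmin(pmax(round(ratings), 1), 7)
  bias <- rowMeans(ratings) - true_size
  expect_lt(max(abs(bias)), 0.1)
})

test_that("null outcomes are standardized noise; planted signs show through", {
  cfg0 <- synthetic_config(
    n_words = 600, seed = 75,
    outcome_specs = list(zrt = list(r2_controls = 0, delta_r2_size = 0,
                                    delta_r2_typicality = 0,
                                    sign_size = 1, sign_typicality = 1))
  )
  lex <- generate_size_ratings(generate_lexicon(cfg0), cfg0)
  ty <- rnorm(600)
  out0 <- generate_outcomes(lex, ty, cfg0)
  expect_equal(mean(out0$zrt), 0, tolerance = 1e-10)
  expect_equal(stats::sd(out0$zrt), 1, tolerance = 1e-10)
  expect_gt(cor.test(out0$zrt, ty)$p.value, 0.001)

  cfg1 <- synthetic_config(
    n_words = 600, seed = 75,
    outcome_specs = list(zrt = list(r2_controls = 0.2, delta_r2_size = 0,
                                    delta_r2_typicality = 0.05,
                                    sign_size = 1, sign_typicality = -1))
  )
  out1 <- generate_outcomes(lex, ty, cfg1)
  expect_lt(cor(out1$zrt, ty), 0)

  # outcome ranges respect their scales
  cfg <- synthetic_config(n_words = 600, seed = 75)
  out <- generate_outcomes(lex, ty, cfg)
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
  expect_true(all(out$corrected_hit >= -1 & out$corrected_hit <= 1))
  expect_setequal(unique(out$category), c("concrete", "abstract"))
})

test_that("written synthetic files are byte-identical across regenerations", {
  cfg <- synthetic_config(n_words = 120, seed = 85)
  dir1 <- file.path(tempdir(), "synthfix1")
  dir2 <- file.path(tempdir(), "synthfix2")
  lex1 <- generate_size_ratings(generate_lexicon(cfg), cfg)
  lex2 <- generate_size_ratings(generate_lexicon(cfg), cfg)
  out1 <- generate_outcomes(lex1, rep(0.5, 120) + lex1$rating_mean / 10, cfg)
  out2 <- generate_outcomes(lex2, rep(0.5, 120) + lex2$rating_mean / 10, cfg)
  p1 <- write_lexicon_files(lex1, dir1, outcomes = out1, config = cfg)
  p2 <- write_lexicon_files(lex2, dir2, outcomes = out2, config = cfg)
  for (key in names(p1)) {
    expect_identical(readLines(p1[[key]]), readLines(p2[[key]]))
  }
  # and the written formats are readable by the pipeline's own readers
  entries <- read_pronunciations(p1[["pronunciations"]])
  expect_equal(nrow(entries), 120L)
  norms <- read_norms(p1[["norms"]])
  expect_equal(norms$word, lex1$orthography)
})
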