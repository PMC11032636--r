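# Seeded synthetic lexicons with planted form-meaning structure: ARPAbet
# pronunciations from simple (onset)(vowel)(coda) syllable templates, Likert
# size ratings driven by a known coefficient vector plus rater noise, and
# item-level behavioural outcomes with controlled R-squared increments.
# Phonotactic realism is not a goal; spanning every phonetic feature
# category is.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% 2147483647L)
  code
}

.child_seed <- function(seed, stage) {
  (as.integer(seed) + stage * 1000003L) %% 2147483647L
}

#' Planted size-model coefficients
#'
#' The generator's default ground truth: an intercept of 3.017 Likert units
#' and 18 nonzero slopes on form variables encoding the size systematicities
#' the pipeline is meant to recover (more syllables and final stress with
#' larger referents, high/mid vowels and initial alveolar/palatal onsets
#' with smaller ones, and so on). All other form variables carry zero.
#'
#' @return Named numeric vector with an `(Intercept)` entry plus slopes.
#' @export
size_model_defaults <- function() {
  c(
    `(Intercept)` = 3.017,
    length_letters = 0.071,
    n_high = -0.113,
    n_mid = -0.066,
    n_labiodental = 0.209,
    n_linguodental = 0.232,
    n_alveolar = 0.076,
    n_palatal = 0.230,
    n_stop = -0.096,
    n_liquid = -0.066,
    first_bilabial = -0.154,
    first_labiodental = -0.199,
    first_alveolar = -0.199,
    first_palatal = -0.425,
    first_voiced = 0.126,
    final_velar = 0.126,
    final_stop = 0.086,
    n_syllables = 0.361,
    stress_final = 0.239
  )
}

#' Default control-covariate distribution
#'
#' Means and SDs of the 13 lexical/semantic control covariates used for
#' synthetic outcome tables (orthographic length, neighbourhood distances,
#' frequency measures, consistency, age of acquisition, prevalence, and the
#' three subjective semantic norms). Covariates are generated as independent
#' normals with these moments.
#'
#' @return Tibble with columns `name`, `mean`, `sd`.
#' @export
covariate_defaults <- function() {
  tibble::tribble(
    ~name, ~mean, ~sd,
    "length", 6.36, 2.01,
    "old", 2.23, 0.76,
    "pld", 2.11, 0.88,
    "bigram_freq", 1043.35, 965.72,
    "zipf_freq", 3.94, 0.73,
    "phonographic_n", 2.13, 3.76,
    "ff_consistency", 0.87, 0.17,
    "fb_consistency", 0.84, 0.18,
    "aoa", 4.10, 1.19,
    "prevalence", 2.32, 0.20,
    "concreteness", 4.41, 1.39,
    "arousal", 4.71, 1.12,
    "valence", 5.20, 1.57
  )
}

#' Configuration of the synthetic-data generator
#'
#' @param n_words Number of words to generate.
#' @param seed Global seed; per-stage child seeds are derived from it so
#'   stages can be regenerated independently.
#' @param syllable_dist Named probabilities of 1..k syllables per word.
#' @param p_onset,p_coda Probability that a syllable carries an onset/coda
#'   consonant.
#' @param onset_inventory,coda_inventory Consonant symbols available in each
#'   position (defaults: the full consonant inventory, so every place,
#'   manner and voicing category is reachable in both word positions).
#' @param p_multi_stress Probability that a multisyllabic word carries two
#'   primary stresses ("even stress").
#' @param p_secondary Probability that a non-primary syllable carries a
#'   secondary-stress digit rather than 0.
#' @param pos_dist Named probabilities over lexical categories.
#' @param p_homograph Probability a word is flagged as the alternative
#'   meaning of a homograph.
#' @param coefficients Planted size-model coefficients (with `(Intercept)`).
#' @param sd_word Word-level noise SD around the linear predictor (Likert
#'   units). The default 1.30 is calibrated so a refit on the rating means
#'   has adjusted R-squared near .20 at n ~ 2,900.
#' @param n_raters Raters per word.
#' @param sd_rater Within-word rater noise SD (Likert units).
#' @param sd_rater_spread SD of per-word variation in `sd_rater` (gamma
#'   distributed); 0 keeps rater noise homogeneous. Raise it to make a
#'   fraction of words exceed the 1.5 rating-SD exclusion cutoff.
#' @param outcome_specs Named list (per dependent variable) of lists with
#'   `r2_controls`, `delta_r2_size`, `delta_r2_typicality`, `sign_size`,
#'   `sign_typicality`: planted cumulative R-squared targets for the
#'   three-step hierarchical regression.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_words = 2924,
    seed = 1L,
    syllable_dist = c(`1` = 0.33, `2` = 0.42, `3` = 0.18, `4` = 0.06, `5` = 0.01),
    p_onset = 0.85,
    p_coda = 0.5,
    onset_inventory = .arpabet_consonants,
    coda_inventory = .arpabet_consonants,
    p_multi_stress = 0.02,
    p_secondary = 0.15,
    pos_dist = c(adjective = 0.19, adverb = 0.015, `function` = 0.01,
                 noun = 0.60, verb = 0.17, name = 0.015),
    p_homograph = 0.02,
    coefficients = size_model_defaults(),
    sd_word = 1.30,
    n_raters = 30L,
    sd_rater = 1.0,
    sd_rater_spread = 0,
    outcome_specs = list(
      zrt = list(r2_controls = 0.45, delta_r2_size = 0.002,
                 delta_r2_typicality = 0.005, sign_size = -1, sign_typicality = -1),
      accuracy = list(r2_controls = 0.15, delta_r2_size = 0.001,
                      delta_r2_typicality = 0.002, sign_size = 1, sign_typicality = 1),
      corrected_hit = list(r2_controls = 0.10, delta_r2_size = 0.005,
                           delta_r2_typicality = 0.001, sign_size = 1, sign_typicality = -1)
    )) {
  if (n_words < 1) stop("n_words must be >= 1", call. = FALSE)
  if (n_raters < 2) stop("n_raters must be >= 2", call. = FALSE)
  if (abs(sum(syllable_dist) - 1) > 1e-8) stop("syllable_dist must sum to 1", call. = FALSE)
  if (abs(sum(pos_dist) - 1) > 1e-8) stop("pos_dist must sum to 1", call. = FALSE)
  if (length(onset_inventory) == 0L || length(coda_inventory) == 0L) {
    stop("onset and coda inventories must be non-empty", call. = FALSE)
  }
  stopifnot(all(onset_inventory %in% .arpabet_consonants),
            all(coda_inventory %in% .arpabet_consonants))
  structure(
    list(
      n_words = as.integer(n_words), seed = as.integer(seed),
      syllable_dist = syllable_dist, p_onset = p_onset, p_coda = p_coda,
      onset_inventory = onset_inventory, coda_inventory = coda_inventory,
      p_multi_stress = p_multi_stress, p_secondary = p_secondary,
      pos_dist = pos_dist, p_homograph = p_homograph,
      coefficients = coefficients, sd_word = sd_word,
      n_raters = as.integer(n_raters), sd_rater = sd_rater,
      sd_rater_spread = sd_rater_spread,
      outcome_specs = outcome_specs
    ),
    class = "synthetic_config"
  )
}

.grapheme_map <- c(
  IY = "ee", IH = "i", UH = "oo", UW = "u", EY = "ai", EH = "e", AH = "u",
  ER = "er", OW = "o", OY = "oy", AE = "a", AA = "ah", AO = "aw", AY = "igh",
  AW = "ow",
  P = "p", B = "b", M = "m", W = "w", F = "f", V = "v", TH = "th", DH = "dh",
  T = "t", D = "d", S = "s", Z = "z", N = "n", L = "l", R = "r", SH = "sh",
  ZH = "zh", CH = "ch", JH = "j", Y = "y", K = "k", G = "g", NG = "ng",
  HH = "h"
)

#' Generate a synthetic lexicon
#'
#' Words are built from (onset)(vowel)(coda) syllable templates with a
#' configurable syllable-count distribution; exactly one syllable carries
#' primary stress except for a small "even stress" fraction with two.
#' Orthography is derived deterministically from the phonemes via a fixed
#' grapheme map (deduplicated with letter suffixes), so letter length and
#' phonological form are naturally correlated. Deterministic under the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `orthography`, `phonemes` (list column, with stress
#'   digits on vowels), `variant_index`, `pos`, `homograph_alternate`.
#' @export
generate_lexicon <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(.child_seed(config$seed, 1L), {
    n <- config$n_words
    n_syll <- sample(as.integer(names(config$syllable_dist)), n, replace = TRUE,
                     prob = config$syllable_dist)
    phonemes <- vector("list", n)
    for (w in seq_len(n)) {
      k <- n_syll[[w]]
      primary <- sample.int(k, 1L)
      extra <- if (k >= 2L && stats::runif(1) < config$p_multi_stress) {
        sample(setdiff(seq_len(k), primary), 1L)
      } else {
        integer()
      }
      syls <- lapply(seq_len(k), function(s) {
        onset <- if (stats::runif(1) < config$p_onset) {
          sample(config$onset_inventory, 1L)
        } else {
          character()
        }
        stress <- if (s %in% c(primary, extra)) {
          "1"
        } else if (stats::runif(1) < config$p_secondary) "2" else "0"
        nucleus <- paste0(sample(.arpabet_vowels, 1L), stress)
        coda <- if (stats::runif(1) < config$p_coda) {
          sample(config$coda_inventory, 1L)
        } else {
          character()
        }
        c(onset, nucleus, coda)
      })
      phonemes[[w]] <- unlist(syls)
    }
    orth <- vapply(phonemes, function(ph) {
      paste(.grapheme_map[strip_stress(ph)$base], collapse = "")
    }, character(1))
    # deduplicate deterministically: append 'x', 'xx', ... until unique
    while (anyDuplicated(orth)) {
      dup <- duplicated(orth)
      orth[dup] <- paste0(orth[dup], "x")
    }
    pos <- sample(names(config$pos_dist), n, replace = TRUE,
                  prob = config$pos_dist)
    tibble::tibble(
      orthography = orth,
      phonemes = phonemes,
      variant_index = 1L,
      pos = pos,
      homograph_alternate = stats::runif(n) < config$p_homograph
    )
  })
}

#' Generate size ratings for a synthetic lexicon
#'
#' The latent size of each word is the planted linear predictor over its
#' form variables plus word-level Gaussian noise. Each of `n_raters`
#' simulated raters reports the latent size plus rater noise, rounded to the
#' nearest integer and clamped to the 1-7 scale; `rating_mean`/`rating_sd`
#' are the across-rater moments.
#'
#' @param lexicon Tibble from [generate_lexicon()].
#' @param config A [synthetic_config()].
#' @return `lexicon` with `true_size`, `rating_mean`, `rating_sd` appended.
#' @export
generate_size_ratings <- function(lexicon, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  features <- build_feature_matrix(lexicon)
  coefs <- config$coefficients
  slopes <- coefs[setdiff(names(coefs), "(Intercept)")]
  unknown <- setdiff(names(slopes), form_feature_names())
  if (length(unknown) > 0L) {
    stop("coefficients on unknown form variables: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  eta <- drop(as.matrix(features[, names(slopes)]) %*% slopes) +
    coefs[["(Intercept)"]]
  .with_seed(.child_seed(config$seed, 2L), {
    n <- nrow(lexicon)
    true_size <- eta + stats::rnorm(n, 0, config$sd_word)
    sd_r <- if (config$sd_rater_spread > 0) {
      shape <- (config$sd_rater / config$sd_rater_spread)^2
      stats::rgamma(n, shape = shape, rate = shape / config$sd_rater)
    } else {
      rep(config$sd_rater, n)
    }
    ratings <- matrix(
      stats::rnorm(n * config$n_raters, mean = true_size, sd = sd_r),
      nrow = n
    )
    ratings <- pmin(pmax(round(ratings), 1), 7)
    dplyr::mutate(
      lexicon,
      true_size = true_size,
      rating_mean = rowMeans(ratings),
      rating_sd = apply(ratings, 1, stats::sd)
    )
  })
}

# residualize v on the columns of M (with intercept), return unit-variance
.resid_std <- function(v, M) {
  fit <- stats::lm.fit(cbind(1, M), v)
  r <- fit$residuals
  r / stats::sd(r)
}

#' Generate behavioural outcome tables with planted effects
#'
#' Control covariates are independent normals with the moments of
#' [covariate_defaults()]. Each dependent variable's latent value is built
#' from three mutually orthogonalized, standardized components -- a controls
#' index, size ratings residualized on the controls, and typicality
#' residualized on controls and size -- with slopes chosen so the three-step
#' hierarchical regression recovers the configured cumulative R-squared and
#' increments in expectation. zRT is standardized across words; accuracy and
#' corrected hit probability are clamped affine maps of their latents into
#' `[0, 1]` and `[-1, 1]`.
#'
#' @param lexicon Tibble with `orthography` and `rating_mean` (run
#'   [generate_size_ratings()] first).
#' @param typicality Numeric vector of typicality z-scores, one per word
#'   (e.g. the `z` column of [compute_typicality()]).
#' @param config A [synthetic_config()].
#' @return Tibble with `word`, the 13 control covariates, `size`,
#'   `typicality`, `category` (concrete/abstract split on concreteness) and
#'   the outcome columns; planted parameters attached as attribute
#'   `"ground_truth"`.
#' @export
generate_outcomes <- function(lexicon, typicality, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(lexicon)
  stopifnot(length(typicality) == n, "rating_mean" %in% names(lexicon))
  covs <- covariate_defaults()
  .with_seed(.child_seed(config$seed, 3L), {
    X <- vapply(seq_len(nrow(covs)), function(i) {
      stats::rnorm(n, covs$mean[[i]], covs$sd[[i]])
    }, numeric(n))
    colnames(X) <- covs$name

    index_w <- c(length = 0.35, zipf_freq = -0.55, aoa = 0.30,
                 prevalence = -0.45, ff_consistency = -0.15)
    u1 <- drop(scale(X[, names(index_w)]) %*% index_w)
    u1 <- u1 / stats::sd(u1)
    u2 <- .resid_std(lexicon$rating_mean, X)
    u3 <- .resid_std(typicality, cbind(X, lexicon$rating_mean))

    truth <- list()
    out <- tibble::tibble(word = lexicon$orthography)
    out <- dplyr::bind_cols(out, tibble::as_tibble(X))
    out$size <- lexicon$rating_mean
    out$typicality <- typicality
    for (dv in names(config$outcome_specs)) {
      spec <- config$outcome_specs[[dv]]
      d1 <- spec$r2_controls
      d2 <- spec$delta_r2_size
      d3 <- spec$delta_r2_typicality
      tot <- 1 / (1 - d1 - d2 - d3)
      a <- sqrt(d1 * tot)
      b <- spec$sign_size * sqrt(d2 * tot)
      cc <- spec$sign_typicality * sqrt(d3 * tot)
      latent <- a * u1 + b * u2 + cc * u3 + stats::rnorm(n)
      val <- switch(
        dv,
        zrt = as.numeric(scale(latent)),
        accuracy = pmin(pmax(0.96 + 0.06 * as.numeric(scale(latent)), 0), 1),
        corrected_hit = pmin(pmax(0.5 + 0.15 * as.numeric(scale(latent)), -1), 1),
        as.numeric(scale(latent))
      )
      out[[dv]] <- val
      truth[[dv]] <- list(slope_controls = a, slope_size = b,
                          slope_typicality = cc,
                          r2_controls = d1, delta_r2_size = d2,
                          delta_r2_typicality = d3)
    }
    out$category <- ifelse(out$concreteness >= stats::median(out$concreteness),
                           "concrete", "abstract")
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Write synthetic inputs in the pipeline's external formats
#'
#' Emits the CMUdict-dialect pronunciation file, the norms CSV, optionally
#' the outcomes CSV, and a ground-truth JSON of all planted parameters.
#'
#' @param lexicon Tibble from [generate_size_ratings()].
#' @param dir Output directory (created if needed).
#' @param outcomes Optional tibble from [generate_outcomes()].
#' @param config The [synthetic_config()] used (stored as ground truth).
#' @return Named character vector of the written paths.
#' @export
write_lexicon_files <- function(lexicon, dir, outcomes = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dict_path <- file.path(dir, "pronunciations.dict")
  lines <- vapply(seq_len(nrow(lexicon)), function(i) {
    paste0(toupper(lexicon$orthography[[i]]), "  ",
           paste(lexicon$phonemes[[i]], collapse = " "))
  }, character(1))
  writeLines(lines, dict_path)

  norms_path <- file.path(dir, "norms.csv")
  norms <- tibble::tibble(
    word = lexicon$orthography,
    size_mean = lexicon$rating_mean,
    size_sd = lexicon$rating_sd,
    pos = lexicon$pos,
    homograph_alternate = lexicon$homograph_alternate
  )
  readr::write_csv(norms, norms_path, progress = FALSE)

  paths <- c(pronunciations = dict_path, norms = norms_path)
  if (!is.null(outcomes)) {
    outcomes_path <- file.path(dir, "outcomes.csv")
    readr::write_csv(outcomes, outcomes_path, progress = FALSE)
    paths <- c(paths, outcomes = outcomes_path)
  }
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- list(
    coefficients = if (!is.null(config)) as.list(config$coefficients) else NULL,
    sd_word = config$sd_word,
    n_raters = config$n_raters,
    sd_rater = config$sd_rater,
    outcome_truth = if (!is.null(outcomes)) attr(outcomes, "ground_truth") else NULL,
    seed = config$seed
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  c(paths, ground_truth = truth_path)
}
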