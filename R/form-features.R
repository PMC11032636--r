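# The 60 surface-form variables: whole-word lengths, phoneme-class counts,
# initial/final phoneme indicators, and primary-stress position.

.place_levels <- c("bilabial", "labiodental", "linguodental", "alveolar",
                   "palatal", "velar", "glottal")
.manner_levels <- c("stop", "fricative", "affricate", "nasal", "liquid", "glide")
.height_levels <- c("high", "mid", "low")
.front_levels <- c("front", "central", "back")

#' Canonical names of the 60 form variables, in matrix column order
#'
#' Order matters: collinearity pruning removes the later-ordered member of
#' each exact dependency, so the column order is part of the contract.
#'
#' @return Character vector of length 60.
#' @export
form_feature_names <- function() {
  c(
    "length_letters", "length_phonemes", "n_syllables",
    paste0("n_", .height_levels),
    paste0("n_", .front_levels),
    paste0("n_", .place_levels),
    paste0("n_", .manner_levels),
    "n_voiced", "n_voiceless",
    "first_is_vowel",
    paste0("first_", .place_levels),
    paste0("first_", .manner_levels),
    "first_voiced", "first_voiceless",
    "final_is_vowel",
    paste0("final_", .place_levels),
    paste0("final_", .manner_levels),
    "final_voiced", "final_voiceless",
    "stress_initial", "stress_final", "stress_medial", "stress_multiple"
  )
}

# Primary-stress position from per-vowel stress digits. Monosyllables and
# words with no primary-stress digit are coded initial; two or more primary
# stresses code as multiple. Secondary stress (digit 2) never plays a role.
.stress_code <- function(stress_digits) {
  n_syll <- length(stress_digits)
  primary <- which(!is.na(stress_digits) & stress_digits == 1L)
  if (length(primary) >= 2L) return("multiple")
  if (n_syll == 1L || length(primary) == 0L || primary[[1]] == 1L) return("initial")
  if (primary[[1]] == n_syll) return("final")
  "medial"
}

#' Extract the 60 form variables for one pronunciation
#'
#' @param phonemes Character vector of ARPAbet symbols with optional stress
#'   digits on vowels.
#' @param n_letters Orthographic length in letters.
#' @param feature_table Decision table; defaults to [arpabet_feature_table()].
#' @return Named numeric vector of length 60 in canonical order.
#' @export
#' @examples
#' extract_features(c("T", "AO1", "L"), n_letters = 4)
extract_features <- function(phonemes, n_letters,
                             feature_table = arpabet_feature_table()) {
  stopifnot(length(phonemes) >= 1L, is.numeric(n_letters))
  ss <- strip_stress(phonemes)
  rows <- match(ss$base, feature_table$symbol)
  if (anyNA(rows)) {
    stop("unknown ARPAbet symbol(s): ",
         paste(unique(ss$base[is.na(rows)]), collapse = ", "), call. = FALSE)
  }
  ft <- feature_table[rows, , drop = FALSE]
  is_vowel <- ft$klass == "vowel"
  n_syll <- sum(is_vowel)
  if (n_syll == 0L) {
    stop("pronunciation has no vowel phoneme; syllable count undefined", call. = FALSE)
  }

  count_of <- function(column, levels) {
    vapply(levels, function(l) sum(ft[[column]] == l), numeric(1))
  }
  indicator_of <- function(i) {
    c(
      is_vowel = as.numeric(is_vowel[[i]]),
      stats::setNames(as.numeric(ft$place[[i]] == .place_levels), .place_levels),
      stats::setNames(as.numeric(ft$manner[[i]] == .manner_levels), .manner_levels),
      voiced = as.numeric(ft$voicing[[i]] == "voiced"),
      voiceless = as.numeric(ft$voicing[[i]] == "voiceless")
    )
  }

  stress_pos <- .stress_code(ss$stress[is_vowel])
  out <- c(
    length_letters = as.numeric(n_letters),
    length_phonemes = length(phonemes),
    n_syllables = n_syll,
    stats::setNames(count_of("height", .height_levels), paste0("n_", .height_levels)),
    stats::setNames(count_of("frontness", .front_levels), paste0("n_", .front_levels)),
    stats::setNames(count_of("place", .place_levels), paste0("n_", .place_levels)),
    stats::setNames(count_of("manner", .manner_levels), paste0("n_", .manner_levels)),
    n_voiced = sum(ft$voicing == "voiced"),
    n_voiceless = sum(ft$voicing == "voiceless"),
    stats::setNames(indicator_of(1L), paste0("first_", c("is_vowel", .place_levels,
                                                         .manner_levels, "voiced", "voiceless"))),
    stats::setNames(indicator_of(nrow(ft)), paste0("final_", c("is_vowel", .place_levels,
                                                               .manner_levels, "voiced", "voiceless"))),
    stress_initial = as.numeric(stress_pos == "initial"),
    stress_final = as.numeric(stress_pos == "final"),
    stress_medial = as.numeric(stress_pos == "medial"),
    stress_multiple = as.numeric(stress_pos == "multiple")
  )
  out[form_feature_names()]
}

#' Build the word-by-feature matrix for a set of retained words
#'
#' One row per word in `words` (or per entry when `words` is `NULL`), columns
#' in the canonical 60-name order. Orthographic length defaults to the letter
#' count of the orthography; an optional `stress_table` (columns `word`,
#' `pattern` with values initial/final/medial/multiple) overrides the stress
#' coding derived from the pronunciation's stress digits.
#'
#' @param entries Tibble from [read_pronunciations()] or [generate_lexicon()].
#' @param words Optional character vector of retained words that must all be
#'   covered by `entries`; errors listing any word without a pronunciation.
#' @param stress_table Optional external stress-pattern table.
#' @param feature_table Decision table.
#' @return Tibble with `word` plus the 60 numeric feature columns.
#' @export
build_feature_matrix <- function(entries, words = NULL, stress_table = NULL,
                                 feature_table = arpabet_feature_table()) {
  if (!is.null(words)) {
    missing <- setdiff(words, entries$orthography)
    if (length(missing) > 0L) {
      stop("no pronunciation for retained word(s): ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else "",
           call. = FALSE)
    }
    entries <- entries[match(words, entries$orthography), , drop = FALSE]
  }
  mat <- .extract_features_bulk(entries$phonemes, nchar(entries$orthography),
                                feature_table)
  out <- dplyr::bind_cols(tibble::tibble(word = entries$orthography),
                          tibble::as_tibble(mat))

  if (!is.null(stress_table)) {
    stopifnot(all(c("word", "pattern") %in% names(stress_table)))
    idx <- match(out$word, stress_table$word)
    hit <- which(!is.na(idx))
    patterns <- stress_table$pattern[idx[hit]]
    bad <- setdiff(unique(patterns), c("initial", "final", "medial", "multiple"))
    if (length(bad) > 0L) stop("unknown stress pattern(s): ", paste(bad, collapse = ", "),
                               call. = FALSE)
    for (col in c("initial", "final", "medial", "multiple")) {
      out[hit, paste0("stress_", col)] <- as.numeric(patterns == col)
    }
  }
  out
}

# Vectorized feature extraction over a whole lexicon. Identical output to
# row-wise extract_features() (asserted by test), but one pass over the
# flattened phoneme stream instead of one call per word.
.extract_features_bulk <- function(phoneme_list, n_letters, feature_table) {
  n <- length(phoneme_list)
  len <- lengths(phoneme_list)
  if (any(len == 0L)) stop("empty pronunciation at entry ",
                           which(len == 0L)[[1]], call. = FALSE)
  word_id <- rep.int(seq_len(n), len)
  sym <- unlist(phoneme_list, use.names = FALSE)
  ss <- strip_stress(sym)
  rows <- match(ss$base, feature_table$symbol)
  if (anyNA(rows)) {
    stop("unknown ARPAbet symbol(s): ",
         paste(unique(ss$base[is.na(rows)]), collapse = ", "), call. = FALSE)
  }
  klass <- feature_table$klass[rows]
  place <- feature_table$place[rows]
  manner <- feature_table$manner[rows]
  voicing <- feature_table$voicing[rows]
  height <- feature_table$height[rows]
  frontness <- feature_table$frontness[rows]
  is_vowel <- klass == "vowel"

  grp_count <- function(flag) {
    out <- numeric(n)
    tab <- rowsum(as.numeric(flag), word_id, reorder = FALSE)
    out[as.integer(rownames(tab))] <- tab[, 1]
    out
  }
  n_syll <- grp_count(is_vowel)
  if (any(n_syll == 0)) {
    stop("pronunciation has no vowel phoneme at entry ",
         which(n_syll == 0)[[1]], "; syllable count undefined", call. = FALSE)
  }

  first_pos <- cumsum(c(1L, len[-n]))
  final_pos <- cumsum(len)

  mat <- matrix(0, nrow = n, ncol = 60L,
                dimnames = list(NULL, form_feature_names()))
  mat[, "length_letters"] <- as.numeric(n_letters)
  mat[, "length_phonemes"] <- as.numeric(len)
  mat[, "n_syllables"] <- n_syll
  for (l in .height_levels) mat[, paste0("n_", l)] <- grp_count(height == l)
  for (l in .front_levels) mat[, paste0("n_", l)] <- grp_count(frontness == l)
  for (l in .place_levels) mat[, paste0("n_", l)] <- grp_count(place == l)
  for (l in .manner_levels) mat[, paste0("n_", l)] <- grp_count(manner == l)
  mat[, "n_voiced"] <- grp_count(voicing == "voiced")
  mat[, "n_voiceless"] <- grp_count(voicing == "voiceless")

  for (side in c("first", "final")) {
    pos <- if (side == "first") first_pos else final_pos
    mat[, paste0(side, "_is_vowel")] <- as.numeric(is_vowel[pos])
    for (l in .place_levels) mat[, paste0(side, "_", l)] <- as.numeric(place[pos] == l)
    for (l in .manner_levels) mat[, paste0(side, "_", l)] <- as.numeric(manner[pos] == l)
    mat[, paste0(side, "_voiced")] <- as.numeric(voicing[pos] == "voiced")
    mat[, paste0(side, "_voiceless")] <- as.numeric(voicing[pos] == "voiceless")
  }

  # stress position: vowel ordinal within word of each primary-stress digit
  prim <- is_vowel & !is.na(ss$stress) & ss$stress == 1L
  n_prim <- grp_count(prim)
  cs <- cumsum(is_vowel)
  vowel_ordinal <- cs - rep.int(c(0, cs[final_pos])[seq_len(n)], len)
  single <- which(n_prim == 1)
  prim_ord <- numeric(n)
  prim_idx <- which(prim)
  one_hit <- prim_idx[word_id[prim_idx] %in% single]
  prim_ord[word_id[one_hit]] <- vowel_ordinal[one_hit]

  code <- rep("initial", n)
  code[n_prim >= 2] <- "multiple"
  sel <- n_prim == 1 & n_syll > 1
  code[sel & prim_ord == n_syll] <- "final"
  code[sel & prim_ord > 1 & prim_ord < n_syll] <- "medial"
  for (s in c("initial", "final", "medial", "multiple")) {
    mat[, paste0("stress_", s)] <- as.numeric(code == s)
  }
  mat
}

#' Write / read a feature matrix as CSV
#'
#' @param features Tibble from [build_feature_matrix()].
#' @param path CSV path.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  read_table_schema(path, required = c("word", form_feature_names()))
}
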