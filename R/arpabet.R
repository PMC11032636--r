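# ARPAbet inventory and the phonetic-feature decision table.
# Diphthongs are classified by nucleus height; AO is treated as a low back
# vowel (the "tall" vowel), matching the size-symbolism convention that low
# vowels pattern with large referents and high vowels with small ones.

.arpabet_vowels <- c(
  "IY", "IH", "UH", "UW", "EY", "EH", "AH", "ER", "OW", "OY",
  "AE", "AA", "AO", "AY", "AW"
)

.arpabet_consonants <- c(
  "P", "B", "M", "W", "F", "V", "TH", "DH", "T", "D", "S", "Z", "N", "L",
  "R", "SH", "ZH", "CH", "JH", "Y", "K", "G", "NG", "HH"
)

.build_feature_table <- function() {
  v_high <- c("IY", "IH", "UH", "UW")
  v_mid <- c("EY", "EH", "AH", "ER", "OW", "OY")
  v_low <- c("AE", "AA", "AO", "AY", "AW")
  v_front <- c("IY", "IH", "EY", "EH", "AE")
  v_central <- c("AH", "ER", "AY")
  v_back <- c("UW", "UH", "OW", "AO", "AA", "AW", "OY")

  place <- c(
    P = "bilabial", B = "bilabial", M = "bilabial", W = "bilabial",
    F = "labiodental", V = "labiodental",
    TH = "linguodental", DH = "linguodental",
    T = "alveolar", D = "alveolar", S = "alveolar", Z = "alveolar",
    N = "alveolar", L = "alveolar", R = "alveolar",
    SH = "palatal", ZH = "palatal", CH = "palatal", JH = "palatal",
    Y = "palatal",
    K = "velar", G = "velar", NG = "velar",
    HH = "glottal"
  )
  manner <- c(
    P = "stop", B = "stop", T = "stop", D = "stop", K = "stop", G = "stop",
    F = "fricative", V = "fricative", TH = "fricative", DH = "fricative",
    S = "fricative", Z = "fricative", SH = "fricative", ZH = "fricative",
    HH = "fricative",
    CH = "affricate", JH = "affricate",
    M = "nasal", N = "nasal", NG = "nasal",
    L = "liquid", R = "liquid",
    W = "glide", Y = "glide"
  )
  voiceless <- c("P", "T", "K", "F", "TH", "S", "SH", "CH", "HH")

  vowels <- tibble::tibble(
    symbol = .arpabet_vowels,
    klass = "vowel",
    place = "none",
    manner = "none",
    voicing = "voiced",
    height = dplyr::case_when(
      .arpabet_vowels %in% v_high ~ "high",
      .arpabet_vowels %in% v_mid ~ "mid",
      .arpabet_vowels %in% v_low ~ "low"
    ),
    frontness = dplyr::case_when(
      .arpabet_vowels %in% v_front ~ "front",
      .arpabet_vowels %in% v_central ~ "central",
      .arpabet_vowels %in% v_back ~ "back"
    )
  )
  consonants <- tibble::tibble(
    symbol = .arpabet_consonants,
    klass = "consonant",
    place = unname(place[.arpabet_consonants]),
    manner = unname(manner[.arpabet_consonants]),
    voicing = ifelse(.arpabet_consonants %in% voiceless, "voiceless", "voiced"),
    height = "none",
    frontness = "none"
  )
  dplyr::bind_rows(vowels, consonants)
}

.feature_table_default <- .build_feature_table()

#' Phonetic feature decision table for the ARPAbet inventory
#'
#' Returns the classification of every ARPAbet symbol into class
#' (vowel/consonant), place and manner of articulation, voicing, and vowel
#' height/frontness. Consonants carry `"none"` for height and frontness;
#' vowels carry `"none"` for place and manner and are always voiced. The
#' table can be replaced (e.g. to move a diphthong between height classes)
#' wherever a `feature_table` argument is accepted.
#'
#' @return A tibble with columns `symbol`, `klass`, `place`, `manner`,
#'   `voicing`, `height`, `frontness`; one row per inventory symbol.
#' @export
#' @examples
#' arpabet_feature_table()
arpabet_feature_table <- function() {
  .feature_table_default
}

#' The ARPAbet symbol inventory
#'
#' @return Character vector of the 39 base symbols (15 vowels, 24 consonants).
#' @export
arpabet_inventory <- function() {
  c(.arpabet_vowels, .arpabet_consonants)
}

#' Strip stress digits from ARPAbet symbols
#'
#' @param symbols Character vector of ARPAbet symbols, possibly carrying a
#'   trailing stress digit (0, 1 or 2) on vowels.
#' @return List with `base` (symbols without digits) and `stress` (integer
#'   stress digit, `NA` where absent).
#' @keywords internal
strip_stress <- function(symbols) {
  has_digit <- grepl("[012]$", symbols)
  base <- sub("[012]$", "", symbols)
  stress <- rep(NA_integer_, length(symbols))
  stress[has_digit] <- as.integer(sub("^.*([012])$", "\\1", symbols[has_digit]))
  list(base = base, stress = stress)
}

#' Classify an ARPAbet phoneme
#'
#' Looks a symbol up in the feature decision table. A trailing stress digit
#' is stripped first. Errors on symbols outside the inventory.
#'
#' @param symbol A single ARPAbet symbol, e.g. `"IY"`, `"AO1"`, `"P"`.
#' @param feature_table Decision table; defaults to [arpabet_feature_table()].
#' @return One-row tibble with the symbol's feature classification.
#' @export
#' @examples
#' classify_phoneme("IY")  # high front vowel
#' classify_phoneme("AO")  # low back vowel
#' classify_phoneme("P")   # voiceless bilabial stop
classify_phoneme <- function(symbol, feature_table = arpabet_feature_table()) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  base <- strip_stress(symbol)$base
  row <- feature_table[feature_table$symbol == base, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown ARPAbet symbol: '", symbol, "'", call. = FALSE)
  }
  row
}
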