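# Readers/writers for pronunciation dictionaries and norms/outcome tables,
# plus the word-exclusion filters applied before modelling.

#' Read a pronunciation lexicon in CMUdict dialect
#'
#' Parses plain-text lines of the form `WORD  PH1 PH2 ...`, where phonemes
#' are ARPAbet symbols with optional stress digits on vowels. Lines starting
#' with `;;;` are comments. Alternate pronunciations are marked `WORD(2)`,
#' `WORD(3)`, ... and carry `variant_index` 2, 3, ...; the unmarked entry is
#' variant 1. Orthography is case-folded to lower case.
#'
#' @param path Path to the dictionary file.
#' @param on_duplicate `"first"` keeps only the primary (variant 1) entry per
#'   word; `"all"` retains every variant.
#' @param feature_table Inventory used to validate symbols.
#' @return Tibble with columns `orthography`, `phonemes` (list column of
#'   character vectors), `variant_index`.
#' @export
read_pronunciations <- function(path, on_duplicate = c("first", "all"),
                                feature_table = arpabet_feature_table()) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("pronunciation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !startsWith(trimws(lines), ";;;") & nzchar(trimws(lines))
  idx <- which(keep)
  inventory <- feature_table$symbol

  entries <- purrr::map(idx, function(i) {
    line <- trimws(lines[[i]])
    parts <- strsplit(line, "\\s+")[[1]]
    if (length(parts) < 2L) {
      stop("malformed dictionary line ", i, ": '", lines[[i]], "'", call. = FALSE)
    }
    head <- parts[[1]]
    phonemes <- parts[-1]
    m <- regmatches(head, regexec("^(.*)\\(([0-9]+)\\)$", head))[[1]]
    if (length(m) == 3L) {
      word <- m[[2]]
      variant <- as.integer(m[[3]])
    } else {
      word <- head
      variant <- 1L
    }
    base <- strip_stress(phonemes)$base
    bad <- setdiff(unique(base), inventory)
    if (length(bad) > 0L) {
      stop(
        "unknown phoneme symbol(s) ", paste0("'", phonemes[base %in% bad], "'", collapse = ", "),
        " on dictionary line ", i,
        call. = FALSE
      )
    }
    stress <- strip_stress(phonemes)$stress
    vowel <- base %in% .arpabet_vowels
    if (any(!is.na(stress) & !vowel)) {
      stop("stress digit on a consonant on dictionary line ", i, call. = FALSE)
    }
    list(orthography = tolower(word), phonemes = phonemes, variant_index = variant)
  })

  out <- tibble::tibble(
    orthography = purrr::map_chr(entries, "orthography"),
    phonemes = purrr::map(entries, "phonemes"),
    variant_index = purrr::map_int(entries, "variant_index")
  )
  if (on_duplicate == "first") {
    out <- out |>
      dplyr::group_by(.data$orthography) |>
      dplyr::slice_min(.data$variant_index, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  out
}

#' Read a semantic-size norms table
#'
#' Expects a CSV with header columns `word`, `size_mean`, `size_sd`, `pos`
#' and optionally `homograph_alternate` (logical flag marking rows that are
#' the alternative meaning of a homograph). Ratings are on a 1-7 Likert
#' scale. Missing values are kept as `NA`.
#'
#' @param path CSV path.
#' @return Tibble of typed norms records.
#' @export
read_norms <- function(path) {
  required <- c("word", "size_mean", "size_sd", "pos")
  tbl <- read_table_schema(path, required)
  tbl <- dplyr::mutate(
    tbl,
    word = tolower(as.character(.data$word)),
    size_mean = as.numeric(.data$size_mean),
    size_sd = as.numeric(.data$size_sd),
    pos = as.character(.data$pos)
  )
  if (!"homograph_alternate" %in% names(tbl)) {
    tbl$homograph_alternate <- FALSE
  } else {
    tbl$homograph_alternate <- as.logical(tbl$homograph_alternate)
  }
  ok <- is.na(tbl$size_mean) | (tbl$size_mean >= 1 & tbl$size_mean <= 7)
  if (!all(ok)) stop("size_mean outside the 1-7 scale at row(s) ",
                     paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
  if (any(tbl$size_sd < 0, na.rm = TRUE)) stop("negative size_sd", call. = FALSE)
  tbl
}

#' Read a CSV against a declared schema
#'
#' Generic carrier for covariate and outcome tables: requires a header row
#' and the named columns; anything extra is kept. Missing cells become `NA`.
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return Tibble.
#' @export
read_table_schema <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Exclusion settings for the norms filter
#'
#' @param sd_threshold Words with rating SD strictly greater than this are
#'   dropped (default 1.5; the boundary value is retained).
#' @param drop_homograph_alternates Drop rows flagged as the alternative
#'   meaning of a homograph.
#' @param drop_proper_names Drop rows whose PoS label is in `name_labels`.
#' @param name_labels PoS labels treated as proper names.
#' @return List of class `exclusion_config`.
#' @export
exclusion_config <- function(sd_threshold = 1.5,
                             drop_homograph_alternates = TRUE,
                             drop_proper_names = TRUE,
                             name_labels = "name") {
  stopifnot(is.numeric(sd_threshold), sd_threshold > 0)
  structure(
    list(
      sd_threshold = sd_threshold,
      drop_homograph_alternates = drop_homograph_alternates,
      drop_proper_names = drop_proper_names,
      name_labels = name_labels
    ),
    class = "exclusion_config"
  )
}

#' Apply the word-exclusion filters to a norms table
#'
#' Stages are applied in order: homograph alternates, then rating-SD filter
#' (strict `> sd_threshold`), then proper names (PoS label match). The
#' per-stage counts are attached as the `"exclusion_report"` attribute and
#' retrievable with [exclusion_report()].
#'
#' @param norms Tibble as returned by [read_norms()].
#' @param config An [exclusion_config()].
#' @return The retained tibble, with an exclusion-report attribute.
#' @export
apply_exclusions <- function(norms, config = exclusion_config()) {
  n_input <- nrow(norms)
  out <- norms
  if (isTRUE(config$drop_homograph_alternates) && "homograph_alternate" %in% names(out)) {
    out <- dplyr::filter(out, !dplyr::coalesce(.data$homograph_alternate, FALSE))
  }
  n_after_homographs <- nrow(out)
  out <- dplyr::filter(out, is.na(.data$size_sd) | .data$size_sd <= config$sd_threshold)
  n_after_sd <- nrow(out)
  if (isTRUE(config$drop_proper_names)) {
    out <- dplyr::filter(out, !(.data$pos %in% config$name_labels))
  }
  n_after_names <- nrow(out)
  report <- tibble::tibble(
    stage = c("input", "homograph_alternates", "sd_filter", "proper_names"),
    n_remaining = c(n_input, n_after_homographs, n_after_sd, n_after_names),
    n_excluded = c(0L, n_input - n_after_homographs,
                   n_after_homographs - n_after_sd,
                   n_after_sd - n_after_names)
  )
  attr(out, "exclusion_report") <- report
  out
}

#' Retrieve the exclusion report from a filtered norms table
#'
#' @param x Result of [apply_exclusions()].
#' @return Tibble of per-stage retained/excluded counts.
#' @export
exclusion_report <- function(x) {
  rep <- attr(x, "exclusion_report", exact = TRUE)
  if (is.null(rep)) stop("no exclusion report attached; run apply_exclusions() first",
                         call. = FALSE)
  rep
}

#' Write an exclusion report as JSON
#'
#' @param report Tibble from [exclusion_report()].
#' @param path Output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
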