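# End-to-end orchestration: the size-model pipeline (read, filter, extract,
# prune, select, score, compare groups) and the megastudy evaluation
# (correlations + hierarchical regressions), with file artifacts.

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.write_manifest <- function(dir, config, extra = list()) {
  manifest <- c(
    list(
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("sizeform")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the size-model pipeline end to end
#'
#' Reads a pronunciation lexicon and a norms table, applies the exclusion
#' filters, drops norms words without a pronunciation (logged), builds the
#' 60-variable feature matrix, prunes exact linear dependencies, selects the
#' best Cp subset, scores typicality, and (when PoS labels are available)
#' compares typicality across lexical categories. Artifacts are written to
#' `output_dir`: `features.csv`, `pruning.json`, `model.json`,
#' `typicality.csv`, `group_stats.json`, `exclusions.json`, `manifest.json`.
#'
#' @param config List (or YAML path) with `pronunciations`, `norms`,
#'   `output_dir`, and optionally `sd_threshold`, `drop_homograph_alternates`,
#'   `drop_proper_names`, `name_labels`, `prune_tol`, `max_features`,
#'   `on_duplicate`.
#' @return Invisibly, a list with the in-memory artifacts (`norms`,
#'   `features`, `pruning`, `model`, `typicality`, `groups`, `n_unmatched`).
#' @export
run_study1 <- function(config) {
  config <- .load_config(config)
  for (field in c("pronunciations", "norms", "output_dir")) {
    if (is.null(config[[field]])) stop("config lacks '", field, "'", call. = FALSE)
  }
  for (field in c("pronunciations", "norms")) {
    if (!file.exists(config[[field]])) {
      stop("input not found: ", config[[field]], call. = FALSE)
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  entries <- read_pronunciations(
    config$pronunciations,
    on_duplicate = config$on_duplicate %||% "first"
  )
  norms <- read_norms(config$norms)
  excl <- exclusion_config(
    sd_threshold = config$sd_threshold %||% 1.5,
    drop_homograph_alternates = config$drop_homograph_alternates %||% TRUE,
    drop_proper_names = config$drop_proper_names %||% TRUE,
    name_labels = config$name_labels %||% "name"
  )
  retained <- apply_exclusions(norms, excl)
  report <- exclusion_report(retained)

  matched <- retained$word %in% entries$orthography
  n_unmatched <- sum(!matched)
  if (n_unmatched > 0) {
    message(n_unmatched, " norms word(s) missing from the pronunciation lexicon; dropped")
  }
  retained <- retained[matched, ]
  if (nrow(retained) == 0L) stop("no words retained after filtering", call. = FALSE)

  features <- build_feature_matrix(entries, words = retained$word)
  pruning <- find_linear_combos(
    features[, form_feature_names()],
    tol = config$prune_tol %||% 1e-8,
    intercept = TRUE
  )
  pruned <- prune_features(features, pruning)

  x <- pruned[, setdiff(names(pruned), "word")]
  model <- best_subset_cp(
    x, retained$size_mean,
    max_features = config$max_features %||% ncol(x)
  )
  typicality <- compute_typicality(model, features)
  scored <- dplyr::bind_cols(typicality, retained[c("pos", "size_mean")])

  groups <- NULL
  major <- dplyr::filter(
    scored, .data$pos %in% c("adjective", "adverb", "function", "noun", "verb")
  )
  if (length(unique(major$pos)) >= 2L && all(table(major$pos) >= 2L)) {
    groups <- compare_groups(major, z, pos)
  }

  write_feature_matrix(features, file.path(config$output_dir, "features.csv"))
  jsonlite::write_json(
    list(removed = pruning$removed, retained = pruning$retained,
         rank = pruning$rank),
    file.path(config$output_dir, "pruning.json"), auto_unbox = TRUE, digits = NA
  )
  write_subset_model(model, file.path(config$output_dir, "model.json"))
  readr::write_csv(scored, file.path(config$output_dir, "typicality.csv"),
                   progress = FALSE)
  write_exclusion_report(report, file.path(config$output_dir, "exclusions.json"))
  if (!is.null(groups)) {
    write_group_comparison(groups, file.path(config$output_dir, "group_stats.json"))
  }
  .write_manifest(config$output_dir, config,
                  list(n_words = nrow(retained), n_unmatched = n_unmatched))

  invisible(list(
    norms = retained, features = features, pruning = pruning, model = model,
    typicality = scored, groups = groups, n_unmatched = n_unmatched,
    exclusions = report
  ))
}

#' Run the megastudy evaluation
#'
#' Zero-order correlations plus a three-step hierarchical regression per
#' dependent variable, optionally split by a category column (separate
#' concrete/abstract analyses). Writes per-dv coefficient tables
#' (`<dv>_coefficients.csv`), a step-summary JSON (`megastudy.json`), the
#' correlation table (`correlations.csv`) and a manifest.
#'
#' @param config List (or YAML path) with `outcomes` (path to the merged
#'   word-level CSV), `output_dir`, `dvs` (character vector of outcome
#'   columns), `controls` (character vector; default the 13 standard
#'   covariates), and optionally `size_var` (default `"size"`),
#'   `typicality_var` (default `"typicality"`), `robust_type`,
#'   `split_column`, `split_values`.
#' @return Invisibly, a list of `hier_fit` objects (nested by split value
#'   when splitting) plus the correlation table.
#' @export
run_megastudy <- function(config) {
  config <- .load_config(config)
  for (field in c("outcomes", "output_dir", "dvs")) {
    if (is.null(config[[field]])) stop("config lacks '", field, "'", call. = FALSE)
  }
  data <- read_table_schema(config$outcomes)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  controls <- config$controls %||% covariate_defaults()$name
  size_var <- config$size_var %||% "size"
  typ_var <- config$typicality_var %||% "typicality"
  missing_cols <- setdiff(c(controls, size_var, typ_var, config$dvs), names(data))
  if (length(missing_cols) > 0L) {
    stop("outcomes table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  cors <- zero_order_correlations(data, c(typ_var, size_var, controls))
  readr::write_csv(tibble::as_tibble(cors),
                   file.path(config$output_dir, "correlations.csv"),
                   progress = FALSE)

  subsets <- if (!is.null(config$split_column)) {
    split_by_category(data, config$split_column, config$split_values)
  } else {
    list(all = data)
  }

  fits <- list()
  summaries <- list()
  for (sub_name in names(subsets)) {
    sub <- subsets[[sub_name]]
    fits[[sub_name]] <- list()
    for (dv in config$dvs) {
      spec <- step_spec(
        blocks = list(controls, size_var, typ_var),
        dv = dv,
        robust_type = config$robust_type %||% "HC2"
      )
      fit <- fit_hierarchical(sub, spec)
      fits[[sub_name]][[dv]] <- fit
      tag <- if (length(subsets) > 1L) paste0(sub_name, "_", dv) else dv
      readr::write_csv(tidy(fit),
                       file.path(config$output_dir,
                                 paste0(tag, "_coefficients.csv")),
                       progress = FALSE)
      summaries[[tag]] <- glance(fit)
    }
  }
  jsonlite::write_json(summaries, file.path(config$output_dir, "megastudy.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  .write_manifest(config$output_dir, config, list(n_rows = nrow(data)))

  invisible(list(fits = fits, correlations = cors))
}
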