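# Best-subset selection of form variables under Mallow's Cp, and the
# typicality scores derived from the selected model's fitted values.

#' Ordinary least squares with intercept
#'
#' Thin wrapper around the QR fit in [stats::lm.fit()] returning the pieces
#' downstream code needs: intercept, slopes, residuals, RSS and adjusted R².
#'
#' @param x Numeric matrix or data frame of predictors (no intercept column).
#' @param y Numeric response.
#' @return List of class `ols_fit` with elements `intercept`, `coefficients`
#'   (named slopes), `fitted`, `residuals`, `rss`, `r_squared`,
#'   `adj_r_squared`, `sigma2`, `n`, `p` (parameters incl. intercept).
#' @export
fit_ols <- function(x, y) {
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  n <- length(y)
  p <- ncol(xm) + 1L
  if (n <= p) stop("need more observations than parameters (n > p)", call. = FALSE)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xm), y)
  if (fit$rank < p) {
    stop("design is rank deficient; remove collinear columns with find_linear_combos()",
         call. = FALSE)
  }
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  structure(
    list(
      intercept = unname(fit$coefficients[[1]]),
      coefficients = fit$coefficients[-1],
      fitted = y - res,
      residuals = res,
      rss = rss,
      r_squared = r2,
      adj_r_squared = adj,
      sigma2 = rss / (n - p),
      n = n,
      p = p
    ),
    class = "ols_fit"
  )
}

#' Select the best feature subset under Mallow's Cp
#'
#' Searches subsets of size 1..`max_features` for the minimizer of
#' `Cp = RSS_p / sigma2_full + 2p - n`, where `p` counts the intercept and
#' `sigma2_full` is the residual variance of the model with every column.
#' The default search is an exact branch-and-bound; `method = "exhaustive"`
#' enumerates all subsets (feasible up to ~20 columns). Ties go to the
#' smaller subset, then to the lexicographically earlier column set. The
#' winning subset is refit by OLS, and the fitted values' mean/SD are stored
#' as the standardization constants later used by [compute_typicality()].
#'
#' @param x Full-column-rank numeric matrix or data frame of candidate
#'   features (prune first with [find_linear_combos()]).
#' @param y Numeric response (size ratings, Likert units).
#' @param max_features Largest subset size searched (default: all columns).
#' @param method `"branch_and_bound"` (default) or `"exhaustive"`.
#' @param tie_eps Absolute Cp tolerance treated as a tie.
#' @return Object of class `subset_model`.
#' @export
best_subset_cp <- function(x, y, max_features = ncol(as.matrix(x)),
                           method = c("branch_and_bound", "exhaustive"),
                           tie_eps = 1e-7) {
  method <- match.arg(method)
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  y <- as.numeric(y)
  stopifnot(nrow(xm) == length(y))
  if (anyNA(xm) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  k <- ncol(xm)
  n <- nrow(xm)
  if (n <= k + 1) stop("need n > number of candidate features + 1", call. = FALSE)
  if (qr(cbind(1, xm))$rank < k + 1) {
    stop("x has linearly dependent columns (with intercept); ",
         "prune with find_linear_combos() first", call. = FALSE)
  }
  max_features <- min(max_features, k)
  stopifnot(max_features >= 1)

  res <- cpp_best_subset(xm, y, max_features, method, tie_eps)
  sel <- colnames(xm)[res$selected]
  refit <- fit_ols(xm[, sel, drop = FALSE], y)

  structure(
    list(
      selected = sel,
      intercept = refit$intercept,
      coefficients = refit$coefficients,
      cp = res$cp,
      adj_r_squared = refit$adj_r_squared,
      r_squared = refit$r_squared,
      rss = refit$rss,
      sigma2_full = res$sigma2_full,
      n = n,
      p = length(sel) + 1L,
      n_candidates = k,
      candidate_names = colnames(xm),
      typicality_center = mean(refit$fitted),
      typicality_scale = stats::sd(refit$fitted),
      method = method,
      nodes = res$nodes,
      fit = refit
    ),
    class = "subset_model"
  )
}

#' Construct a subset model directly from known coefficients
#'
#' Useful for scoring words under a published or planted coefficient set
#' without refitting.
#'
#' @param intercept Intercept (Likert units).
#' @param coefficients Named numeric vector of slopes.
#' @param center,scale Optional standardization constants for z-scores.
#' @return Object of class `subset_model` (without fit diagnostics).
#' @export
subset_model <- function(intercept, coefficients, center = NULL, scale = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  structure(
    list(
      selected = names(coefficients),
      intercept = intercept,
      coefficients = coefficients,
      cp = NA_real_,
      adj_r_squared = NA_real_,
      r_squared = NA_real_,
      rss = NA_real_,
      sigma2_full = NA_real_,
      n = NA_integer_,
      p = length(coefficients) + 1L,
      n_candidates = NA_integer_,
      candidate_names = names(coefficients),
      typicality_center = center,
      typicality_scale = scale,
      method = "external",
      nodes = NA_real_,
      fit = NULL
    ),
    class = "subset_model"
  )
}

#' @export
print.subset_model <- function(x, ...) {
  cat("Best-subset size model (Cp criterion)\n")
  cat(sprintf("  %d of %s candidate features selected; Cp = %.3f; adj. R^2 = %.3f\n",
              length(x$selected),
              ifelse(is.na(x$n_candidates), "?", x$n_candidates),
              x$cp, x$adj_r_squared))
  cat("  Features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.subset_model <- function(x, ...) {
  est <- c(`(Intercept)` = x$intercept, x$coefficients)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' @export
glance.subset_model <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    cp = x$cp,
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    sigma2_full = x$sigma2_full,
    n = x$n,
    p = x$p
  )
}

#' Form-typicality scores from a fitted size model
#'
#' The typicality of a word is the model's fitted (predicted) size for its
#' form variables; positive z-scores indicate forms typical of larger
#' referents. Standardization constants come from the fitting set (stored on
#' the model), so new words are scored on the same scale.
#'
#' @param model A `subset_model`.
#' @param features Feature table covering the model's selected columns; a
#'   `word` column, if present, is carried through.
#' @return Tibble of class `typicality_scores` with `word` (if available),
#'   `fitted` (Likert units) and `z`.
#' @export
compute_typicality <- function(model, features) {
  stopifnot(inherits(model, "subset_model"))
  feats <- tibble::as_tibble(features)
  missing <- setdiff(model$selected, names(feats))
  if (length(missing) > 0L) {
    stop("features table lacks model column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(feats[, model$selected, drop = FALSE])
  fitted <- drop(model$intercept + xm %*% model$coefficients[model$selected])
  center <- model$typicality_center
  scale <- model$typicality_scale
  if (is.null(center) || is.null(scale)) {
    center <- mean(fitted)
    scale <- stats::sd(fitted)
  }
  if (!is.finite(scale) || scale == 0) {
    stop("fitted values have zero spread; typicality is degenerate", call. = FALSE)
  }
  out <- tibble::tibble(fitted = fitted, z = (fitted - center) / scale)
  if ("word" %in% names(feats)) out <- dplyr::bind_cols(feats["word"], out)
  class(out) <- c("typicality_scores", class(out))
  out
}

#' @export
autoplot.typicality_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::labs(x = "form typicality (z)", y = "words") +
    ggplot2::theme_minimal()
}

#' Serialize / restore a subset model as JSON
#'
#' The JSON carries column names, intercept and slopes, Cp, sample size and
#' the standardization constants, so that scoring is bit-for-bit
#' reproducible from the file alone.
#'
#' @param model A `subset_model`.
#' @param path Output path.
#' @export
write_subset_model <- function(model, path) {
  payload <- list(
    selected = model$selected,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    cp = model$cp,
    adj_r_squared = model$adj_r_squared,
    r_squared = model$r_squared,
    sigma2_full = model$sigma2_full,
    n = model$n,
    p = model$p,
    typicality_center = model$typicality_center,
    typicality_scale = model$typicality_scale
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subset_model
#' @export
read_subset_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- subset_model(
    intercept = payload$intercept,
    coefficients = unlist(payload$coefficients),
    center = payload$typicality_center,
    scale = payload$typicality_scale
  )
  m$cp <- payload$cp
  m$adj_r_squared <- payload$adj_r_squared
  m$r_squared <- payload$r_squared
  m$sigma2_full <- payload$sigma2_full
  m$n <- payload$n
  m$p <- payload$p
  m
}
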