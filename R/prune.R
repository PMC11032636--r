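# Removal of exactly collinear feature columns before subset selection.

#' Find and remove exact linear dependencies among columns
#'
#' Greedy left-to-right rank check: a column is removed when it lies (to
#' tolerance) in the span of the retained earlier columns, so the
#' later-ordered member of every dependency is the one dropped. With
#' `intercept = TRUE` (default) the constant vector is included in the span
#' (but never removable), which also eliminates sum-to-one indicator
#' identities that would otherwise alias the intercept of a downstream
#' regression.
#'
#' @param x Numeric matrix or data frame of feature columns.
#' @param tol Relative tolerance for declaring a residual zero (default
#'   1e-8), applied after scaling each column.
#' @param intercept Include the constant vector in the spanning set.
#' @return List of class `pruning_result`: `removed` and `retained` column
#'   names, and the achieved `rank` (number of retained columns).
#' @export
find_linear_combos <- function(x, tol = 1e-8, intercept = TRUE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric", call. = FALSE)
  if (ncol(m) < 1L) stop("x needs at least one column", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  n <- nrow(m)

  q <- matrix(0, n, 0)
  if (intercept) q <- cbind(q, rep(1 / sqrt(n), n))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    nrm <- sqrt(sum(v^2))
    if (nrm <= tol) next  # zero column: dependent by convention
    v <- v / nrm
    # two rounds of Gram-Schmidt for numerical stability
    for (pass in 1:2) if (ncol(q) > 0L) v <- v - q %*% crossprod(q, v)
    res <- sqrt(sum(v^2))
    if (res > tol) {
      keep[j] <- TRUE
      q <- cbind(q, v / res)
    }
  }
  structure(
    list(
      removed = colnames(m)[!keep],
      retained = colnames(m)[keep],
      rank = sum(keep)
    ),
    class = "pruning_result"
  )
}

#' @export
print.pruning_result <- function(x, ...) {
  cat("Pruning result: rank", x$rank, "of", x$rank + length(x$removed),
      "columns\n")
  if (length(x$removed) > 0L) {
    cat("Removed:", paste(x$removed, collapse = ", "), "\n")
  } else {
    cat("No columns removed\n")
  }
  invisible(x)
}

#' Apply a pruning result to a feature table
#'
#' @param features Tibble with a `word` column plus feature columns, or a
#'   plain matrix/data frame of features.
#' @param pruning A `pruning_result` from [find_linear_combos()].
#' @return The input with removed columns dropped.
#' @export
prune_features <- function(features, pruning) {
  stopifnot(inherits(pruning, "pruning_result"))
  dplyr::select(tibble::as_tibble(features), -dplyr::any_of(pruning$removed))
}
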