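# Three-step hierarchical OLS with heteroskedasticity-consistent standard
# errors: lexical/semantic controls first, then size ratings, then form
# typicality; per-step robust coefficient tables, adjusted R-squared and the
# R-squared increment with a robust Wald test on the added block.

#' Specification of a hierarchical regression
#'
#' @param blocks Ordered list of character vectors; block `k` is added at
#'   step `k` (models are cumulative). Blocks must be disjoint.
#' @param dv Name of the dependent variable; must not appear in any block.
#' @param robust_type Sandwich estimator: `"HC0"`, `"HC1"`, `"HC2"` (default)
#'   or `"HC3"`.
#' @param center_predictors Mean-centre all predictors before fitting
#'   (default `TRUE`); slopes and R-squared are unaffected, only the
#'   intercept moves.
#' @param standardize_dv z-score the dependent variable first.
#' @return List of class `step_spec`.
#' @export
step_spec <- function(blocks, dv,
                      robust_type = c("HC2", "HC0", "HC1", "HC3"),
                      center_predictors = TRUE, standardize_dv = FALSE) {
  robust_type <- match.arg(robust_type)
  stopifnot(is.list(blocks), length(blocks) >= 1L,
            all(vapply(blocks, is.character, logical(1))))
  all_preds <- unlist(blocks)
  if (anyDuplicated(all_preds)) {
    stop("predictor blocks must be disjoint; duplicated: ",
         paste(unique(all_preds[duplicated(all_preds)]), collapse = ", "),
         call. = FALSE)
  }
  if (dv %in% all_preds) stop("dv must not appear among the predictors", call. = FALSE)
  structure(
    list(blocks = blocks, dv = dv, robust_type = robust_type,
         center_predictors = center_predictors, standardize_dv = standardize_dv),
    class = "step_spec"
  )
}

#' Heteroskedasticity-consistent coefficient covariance
#'
#' Sandwich covariance of an [stats::lm()] fit. HC0 is the plain
#' White estimator; HC1 rescales by `n/(n-p)`; HC2 and HC3 weight squared
#' residuals by `1/(1-h_i)` and `1/(1-h_i)^2`. Errors when a leverage
#' equals 1 under HC2/HC3, naming the observation.
#'
#' @param fit An `lm` object.
#' @param robust_type One of `"HC0"`, `"HC1"`, `"HC2"`, `"HC3"`.
#' @return Coefficient covariance matrix.
#' @export
robust_covariance <- function(fit, robust_type = c("HC2", "HC0", "HC1", "HC3")) {
  robust_type <- match.arg(robust_type)
  stopifnot(inherits(fit, "lm"))
  if (robust_type %in% c("HC2", "HC3")) {
    h <- stats::hatvalues(fit)
    bad <- which(1 - h <= .Machine$double.eps^0.5)
    if (length(bad) > 0L) {
      stop("leverage of 1 at observation(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; ", robust_type, " is undefined there", call. = FALSE)
    }
  }
  sandwich::vcovHC(fit, type = robust_type)
}

#' Fit a hierarchical regression with robust standard errors
#'
#' Step `k` regresses the dv on the union of blocks 1..k. Rows with missing
#' values on the dv or any predictor are dropped listwise (count recorded).
#' Each step reports coefficients with robust SEs, t ratios and p-values,
#' the step's R-squared and adjusted R-squared, the increment in unadjusted
#' R-squared over the previous step, and a robust Wald chi-squared test on
#' the newly added block.
#'
#' @param data Data frame holding the dv and all predictors.
#' @param spec A [step_spec()].
#' @return Object of class `hier_fit`.
#' @export
fit_hierarchical <- function(data, spec) {
  stopifnot(inherits(spec, "step_spec"))
  df <- tibble::as_tibble(data)
  vars <- c(spec$dv, unlist(spec$blocks))
  missing_cols <- setdiff(vars, names(df))
  if (length(missing_cols) > 0L) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, vars]
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, ]
  n <- nrow(df)

  preds <- unlist(spec$blocks)
  if (spec$center_predictors) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(preds), ~ .x - mean(.x)))
  }
  if (spec$standardize_dv) {
    df[[spec$dv]] <- as.numeric(scale(df[[spec$dv]]))
  }

  steps <- vector("list", length(spec$blocks))
  prev_r2 <- NA_real_
  for (k in seq_along(spec$blocks)) {
    cur_preds <- unlist(spec$blocks[seq_len(k)])
    if (n <= length(cur_preds) + 1L) {
      stop("step ", k, ": need n > number of parameters", call. = FALSE)
    }
    fml <- stats::reformulate(sprintf("`%s`", cur_preds),
                              response = sprintf("`%s`", spec$dv))
    fit <- stats::lm(fml, data = df)
    if (fit$rank < length(cur_preds) + 1L) {
      stop("step ", k, ": collinear predictor block; prune with find_linear_combos()",
           call. = FALSE)
    }
    V <- robust_covariance(fit, spec$robust_type)
    b <- stats::coef(fit)
    se <- sqrt(diag(V))
    sm <- summary(fit)
    r2 <- sm$r.squared
    coef_tbl <- tibble::tibble(
      term = names(b),
      estimate = unname(b),
      se_robust = unname(se),
      statistic = unname(b / se),
      p_value = 2 * stats::pt(abs(unname(b / se)), df = fit$df.residual,
                              lower.tail = FALSE)
    )

    delta_r2 <- if (k == 1L) NA_real_ else r2 - prev_r2
    if (k == 1L) {
      delta_chisq <- NA_real_
      delta_df <- NA_integer_
      delta_p <- NA_real_
    } else {
      new_terms <- spec$blocks[[k]]
      idx <- match(new_terms, names(b))
      bb <- b[idx]
      Vb <- V[idx, idx, drop = FALSE]
      delta_chisq <- drop(t(bb) %*% solve(Vb, bb))
      delta_df <- length(idx)
      delta_p <- stats::pchisq(delta_chisq, df = delta_df, lower.tail = FALSE)
    }

    steps[[k]] <- list(
      step = k,
      terms = cur_preds,
      added = spec$blocks[[k]],
      coefficients = coef_tbl,
      r_squared = r2,
      adj_r_squared = sm$adj.r.squared,
      delta_r2 = delta_r2,
      delta_chisq = delta_chisq,
      delta_df = delta_df,
      delta_p = delta_p,
      fit = fit
    )
    prev_r2 <- r2
  }

  structure(
    list(steps = steps, spec = spec, n = n, n_dropped = n_dropped),
    class = "hier_fit"
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("Hierarchical regression of %s (%d steps, n = %d, %s robust SEs",
              x$spec$dv, length(x$steps), x$n, x$spec$robust_type))
  if (x$n_dropped > 0) cat(sprintf(", %d rows dropped listwise", x$n_dropped))
  cat(")\n")
  for (s in x$steps) {
    cat(sprintf("  Step %d: adj R^2 = %.4f", s$step, s$adj_r_squared))
    if (!is.na(s$delta_r2)) {
      cat(sprintf(", dR^2 = %.4f (Wald chi^2(%d) = %.2f, p = %.3g)",
                  s$delta_r2, s$delta_df, s$delta_chisq, s$delta_p))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.hier_fit <- function(x, ...) {
  purrr::map_dfr(x$steps, function(s) {
    dplyr::bind_cols(tibble::tibble(step = s$step), s$coefficients)
  })
}

#' @export
glance.hier_fit <- function(x, ...) {
  purrr::map_dfr(x$steps, function(s) {
    tibble::tibble(
      step = s$step,
      r_squared = s$r_squared,
      adj_r_squared = s$adj_r_squared,
      delta_r2 = s$delta_r2,
      delta_chisq = s$delta_chisq,
      delta_df = s$delta_df,
      delta_p = s$delta_p,
      n = x$n
    )
  })
}

#' @export
autoplot.hier_fit <- function(object, step = length(object$steps), ...) {
  tbl <- object$steps[[step]]$coefficients
  tbl <- tbl[tbl$term != "(Intercept)", ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se_robust,
                   xmax = .data$estimate + 1.96 * .data$se_robust),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "estimate (robust 95% CI)", y = NULL,
                  title = sprintf("Step %d coefficients", step)) +
    ggplot2::theme_minimal()
}

#' Zero-order Pearson correlations with p-values
#'
#' Pairwise-complete Pearson correlations for the named variables, with
#' two-sided p-values. Zero-variance variables yield `NA` entries flagged in
#' the `degenerate` column rather than an error.
#'
#' @param data Data frame.
#' @param variables Character vector of numeric columns (default: all
#'   numeric columns).
#' @return Tibble of class `cor_table` with one row per unordered pair:
#'   `var1`, `var2`, `r`, `n`, `p_value`, `degenerate`. The full symmetric
#'   matrix is attached as attribute `"matrix"`.
#' @export
zero_order_correlations <- function(data, variables = NULL) {
  df <- tibble::as_tibble(data)
  if (is.null(variables)) {
    variables <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(variables, names(df))
  if (length(missing_cols) > 0L) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  k <- length(variables)
  stopifnot(k >= 2L)
  mat <- diag(1, k)
  dimnames(mat) <- list(variables, variables)
  pairs <- utils::combn(k, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]
    j <- pairs[2, c_idx]
    x <- df[[variables[[i]]]]
    y <- df[[variables[[j]]]]
    ok <- stats::complete.cases(x, y)
    n_ok <- sum(ok)
    degenerate <- n_ok < 3L ||
      stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
    if (degenerate) {
      r <- NA_real_
      p <- NA_real_
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
    mat[i, j] <<- r
    mat[j, i] <<- r
    tibble::tibble(var1 = variables[[i]], var2 = variables[[j]],
                   r = r, n = n_ok, p_value = p, degenerate = degenerate)
  })
  attr(rows, "matrix") <- mat
  class(rows) <- c("cor_table", class(rows))
  rows
}

#' @export
autoplot.cor_table <- function(object, ...) {
  mat <- attr(object, "matrix")
  long <- as.data.frame(as.table(mat), responseName = "r")
  names(long)[1:2] <- c("var1", "var2")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Split a table by the values of a category column
#'
#' @param data Data frame.
#' @param column Column name (string) to split on.
#' @param values Category values wanted (default: all observed). A value
#'   absent from the data yields an empty sub-table with a warning.
#' @return Named list of tibbles, one per value.
#' @export
split_by_category <- function(data, column, values = NULL) {
  df <- tibble::as_tibble(data)
  if (!column %in% names(df)) stop("column not found: ", column, call. = FALSE)
  if (is.null(values)) values <- unique(df[[column]])
  out <- purrr::map(values, function(v) df[df[[column]] %in% v, , drop = FALSE])
  names(out) <- as.character(values)
  empty <- names(out)[vapply(out, nrow, integer(1)) == 0L]
  if (length(empty) > 0L) {
    warning("no rows for value(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}
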