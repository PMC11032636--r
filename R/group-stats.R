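# Comparison of typicality across lexical categories: homogeneity check,
# Welch's ANOVA with an omega-squared effect size, and Games-Howell
# pairwise post hocs for unequal variances and group sizes.

.group_split_values <- function(data, value, group) {
  df <- tibble::as_tibble(data)
  v <- dplyr::pull(df, {{ value }})
  g <- dplyr::pull(df, {{ group }})
  ok <- !is.na(v) & !is.na(g)
  split(v[ok], as.character(g[ok]))
}

.check_groups <- function(groups, need_var = TRUE) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(groups)[ns < 2L], collapse = ", "), call. = FALSE)
  }
  if (need_var) {
    vs <- vapply(groups, stats::var, numeric(1))
    if (any(vs <= 0)) {
      stop("group(s) with zero variance: ",
           paste(names(groups)[vs <= 0], collapse = ", "), call. = FALSE)
    }
  }
  invisible(groups)
}

#' Bartlett's test of homogeneity of variance
#'
#' @param data Data frame in long format.
#' @param value,group Bare column names of the measured variable and the
#'   grouping factor.
#' @return One-row tibble: `statistic` (chi-squared), `df`, `p_value`.
#' @export
bartlett_test <- function(data, value, group) {
  groups <- .group_split_values(data, {{ value }}, {{ group }})
  .check_groups(groups)
  ht <- stats::bartlett.test(groups)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = as.integer(unname(ht$parameter)),
    p_value = ht$p.value
  )
}

#' Welch's one-way ANOVA with omega-squared
#'
#' Heteroskedasticity-robust one-way ANOVA (Welch F with Satterthwaite
#' denominator df) plus the conventional effect-size approximation
#' `omega2 = df1 (F - 1) / (df1 (F - 1) + N)`, which is approximate when
#' applied to the Welch statistic.
#'
#' @inheritParams bartlett_test
#' @return One-row tibble: `f`, `df1`, `df2`, `p_value`, `omega2`, `n`.
#' @export
welch_anova <- function(data, value, group) {
  groups <- .group_split_values(data, {{ value }}, {{ group }})
  .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  ht <- stats::oneway.test(x ~ g, var.equal = FALSE)
  n <- length(x)
  f <- unname(ht$statistic)
  df1 <- unname(ht$parameter[[1]])
  omega2 <- df1 * (f - 1) / (df1 * (f - 1) + n)
  tibble::tibble(
    f = f,
    df1 = as.integer(df1),
    df2 = unname(ht$parameter[[2]]),
    p_value = ht$p.value,
    omega2 = omega2,
    n = n
  )
}

#' Games-Howell pairwise post hoc comparisons
#'
#' For each pair of groups, the Welch-type standard error
#' `sqrt(s2_i/n_i + s2_j/n_j)` with Satterthwaite degrees of freedom; the
#' studentized-range statistic is `q = |diff| * sqrt(2) / SE` and the
#' adjusted p-value comes from the studentized-range distribution with the
#' full number of groups, so the family of all pairwise comparisons is
#' controlled.
#'
#' @inheritParams bartlett_test
#' @return Tibble with one row per unordered pair: `group1`, `group2`,
#'   `mean_diff` (group1 - group2), `se`, `df`, `q`, `p_adj`.
#' @export
games_howell <- function(data, value, group) {
  groups <- .group_split_values(data, {{ value }}, {{ group }})
  .check_groups(groups)
  k <- length(groups)
  labs <- names(groups)
  ns <- lengths(groups)
  ms <- vapply(groups, mean, numeric(1))
  vs <- vapply(groups, stats::var, numeric(1))

  pairs <- utils::combn(seq_len(k), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]
    j <- pairs[2, c_idx]
    vi <- vs[[i]] / ns[[i]]
    vj <- vs[[j]] / ns[[j]]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (ns[[i]] - 1) + vj^2 / (ns[[j]] - 1))
    diff <- ms[[i]] - ms[[j]]
    q <- abs(diff) * sqrt(2) / se
    tibble::tibble(
      group1 = labs[[i]],
      group2 = labs[[j]],
      mean_diff = diff,
      se = se,
      df = df,
      q = q,
      p_adj = stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    )
  })
}

#' Full group comparison of typicality by lexical category
#'
#' Runs [bartlett_test()], [welch_anova()] and [games_howell()] and bundles
#' the three result tables.
#'
#' @inheritParams bartlett_test
#' @return List of class `group_comparison` with elements `bartlett`,
#'   `welch`, `games_howell`, and `group_summary` (n, mean, sd per group).
#' @export
compare_groups <- function(data, value, group) {
  groups <- .group_split_values(data, {{ value }}, {{ group }})
  .check_groups(groups)
  summary <- tibble::tibble(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1))
  )
  structure(
    list(
      bartlett = bartlett_test(data, {{ value }}, {{ group }}),
      welch = welch_anova(data, {{ value }}, {{ group }}),
      games_howell = games_howell(data, {{ value }}, {{ group }}),
      group_summary = summary
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison\n")
  cat(sprintf("  Bartlett chi^2(%d) = %.3f, p = %.3g\n",
              x$bartlett$df, x$bartlett$statistic, x$bartlett$p_value))
  cat(sprintf("  Welch F(%d, %.1f) = %.3f, p = %.3g, omega^2 = %.4f\n",
              x$welch$df1, x$welch$df2, x$welch$f, x$welch$p_value,
              x$welch$omega2))
  sig <- sum(x$games_howell$p_adj < 0.05)
  cat(sprintf("  Games-Howell: %d of %d pairs with p_adj < .05\n",
              sig, nrow(x$games_howell)))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  x$games_howell
}

#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::bind_cols(
    x$welch,
    tibble::tibble(bartlett_chi2 = x$bartlett$statistic,
                   bartlett_p = x$bartlett$p_value)
  )
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$group_summary,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = NULL, y = "mean (+/- SD)") +
    ggplot2::theme_minimal()
}

#' Write a group-comparison report as JSON
#'
#' @param comparison A `group_comparison`.
#' @param path Output path.
#' @export
write_group_comparison <- function(comparison, path) {
  jsonlite::write_json(
    list(
      bartlett = comparison$bartlett,
      welch = comparison$welch,
      games_howell = comparison$games_howell,
      group_summary = comparison$group_summary
    ),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
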