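# Shared fixtures: tiny in-code dictionaries and norms tables, a random
# regression-problem builder, and a plain-R exhaustive Cp oracle kept
# deliberately independent of the package's search code.

tiny_dict_lines <- function() {
  c(
    ";;; fixture dictionary",
    "TALL  T AO1 L",
    "TEENSY  T IY1 N Z IY0",
    "MITE  M AY1 T",
    "MOTE  M OW1 T",
    "ECHO  EH1 K OW0",
    "SODA  S OW1 D AH0",
    "THE  DH AH0",
    "BALLOON  B AH0 L UW1 N",
    "BALLOON(2)  B L UW1 N",
    "GIGANTIC  JH AY0 G AE1 N T IH0 K"
  )
}

write_tiny_dict <- function(path = tempfile(fileext = ".dict"),
                            lines = tiny_dict_lines()) {
  writeLines(lines, path)
  path
}

tiny_norms <- function() {
  tibble::tibble(
    word = c("tall", "teensy", "mite", "mote", "echo", "soda", "the",
             "balloon", "gigantic"),
    size_mean = c(5.8, 1.4, 1.2, 2.0, 3.1, 3.0, 3.5, 4.9, 6.7),
    size_sd = c(0.9, 0.7, 0.6, 1.5, 1.6, 1.1, 1.8, 1.0, 0.5),
    pos = c("adjective", "adjective", "noun", "noun", "noun", "noun",
            "function", "noun", "name"),
    homograph_alternate = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                            FALSE, FALSE)
  )
}

# random full-rank regression problem with a sparse planted signal
random_problem <- function(n, k, n_signal = min(3L, k), sigma = 1,
                           rho = 0) {
  x <- matrix(stats::rnorm(n * k), n, k)
  if (rho > 0) {
    z <- stats::rnorm(n)
    x <- sqrt(1 - rho) * x + sqrt(rho) * z
  }
  colnames(x) <- sprintf("v%02d", seq_len(k))
  beta <- c(stats::runif(n_signal, 0.5, 2) * sample(c(-1, 1), n_signal, TRUE),
            rep(0, k - n_signal))
  y <- drop(x %*% beta) + stats::rnorm(n, 0, sigma)
  list(x = x, y = y, beta = beta)
}

# Exhaustive Cp minimizer by direct enumeration: for every nonempty subset,
# RSS from the normal equations on the centred Gram system. Ties resolve to
# the smaller, then lexicographically earlier, subset -- the documented
# convention.
oracle_best_subset <- function(x, y, max_features = ncol(x), tie_eps = 1e-7) {
  x <- as.matrix(x)
  k <- ncol(x)
  n <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(xc)
  g <- drop(crossprod(xc, yc))
  yy <- sum(yc^2)
  rss_of <- function(idx) {
    yy - drop(crossprod(g[idx], solve(G[idx, idx, drop = FALSE], g[idx])))
  }
  sigma2 <- rss_of(seq_len(k)) / (n - k - 1)
  best_cp <- Inf
  best_idx <- NULL
  for (mask in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1, seq_len(k) - 1)) > 0)
    if (length(idx) > max_features) next
    cp <- rss_of(idx) / sigma2 + 2 * (length(idx) + 1) - n
    better <- cp < best_cp - tie_eps
    tie <- abs(cp - best_cp) <= tie_eps &&
      (length(idx) < length(best_idx) ||
         (length(idx) == length(best_idx) &&
            paste(idx, collapse = ",") < paste(best_idx, collapse = ",")))
    if (better || tie) {
      best_cp <- cp
      best_idx <- idx
    }
  }
  list(selected = colnames(x)[best_idx], cp = best_cp)
}

# independent Welch ANOVA from the textbook formula
welch_by_hand <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  a <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  f <- a / (1 + 2 * lam * (k - 2))
  df2 <- 1 / (3 * lam)
  p <- stats::pf(f, k - 1, df2, lower.tail = FALSE)
  list(f = f, df1 = k - 1, df2 = df2, p = p)
}

# independent Bartlett statistic from the textbook formula
bartlett_by_hand <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  vi <- vapply(groups, stats::var, numeric(1))
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  den <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}

groups_to_df <- function(groups) {
  tibble::tibble(
    value = unlist(groups, use.names = FALSE),
    grp = rep(names(groups), lengths(groups))
  )
}
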