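#' D'Agostino–Pearson omnibus normality test
#'
#' The omnibus K^2 statistic combines the sample-size-corrected
#' skewness Z (D'Agostino's transformation of sqrt(b1)) and kurtosis Z
#' (the Anscombe–Glynn transformation of b2); under normality
#' K^2 = Zs^2 + Zk^2 is approximately chi-squared with 2 degrees of
#' freedom. The moment approximations require n >= 8.
#'
#' @param x Numeric vector, n >= 8.
#' @return List: `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("dagostino_pearson() requires n >= 8.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Normality-gated two-group comparison
#'
#' The conventional gate for touchscreen endpoint measures: each group is
#' screened with the D'Agostino–Pearson omnibus test; if both groups are
#' consistent with normality the groups are compared with Welch's t test
#' (unequal variances), otherwise with the Mann–Whitney U test. For
#' groups too small for the omnibus moment approximations (n < 8) the
#' gate falls back to the Shapiro–Wilk test.
#'
#' No multiple-testing correction is applied across measures; reports
#' that batch several comparisons carry a note to that effect.
#'
#' @param x,y Numeric samples for the two groups (n >= 3 each).
#' @param alpha Significance level of the comparison (recorded, default
#'   0.05).
#' @param normality_alpha Gate level for the normality screen (default
#'   0.05).
#' @param labels Character pair naming the groups.
#' @param measure Optional measure name carried into the result.
#' @return One-row tibble: `measure`, `group1`, `group2`, `n1`, `n2`,
#'   `normality_p1`, `normality_p2`, `test_used` (`"welch_t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `significant`.
#' @export
compare_groups <- function(x, y, alpha = 0.05, normality_alpha = 0.05,
                           labels = c("group1", "group2"),
                           measure = NA_character_) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("compare_groups() requires at least 3 values per group.")
  }
  norm_p <- function(v) {
    if (sd(v) == 0) return(0)  # degenerate sample: clearly non-normal
    if (length(v) >= 8) dagostino_pearson(v)$p_value
    else stats::shapiro.test(v)$p.value
  }
  p1 <- norm_p(x)
  p2 <- norm_p(y)
  if (identical(x[order(x)], y[order(y)])) {
    # identical samples: the difference is exactly zero
    test_used <- "welch_t"
    statistic <- 0
    p_value <- 1
  } else if (p1 >= normality_alpha && p2 >= normality_alpha) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    test_used <- "welch_t"
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  } else {
    # ties force the normal approximation; the warning is routine for
    # count-valued endpoints, so it is not propagated
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              correct = TRUE))
    test_used <- "mann_whitney"
    statistic <- unname(wt$statistic)
    p_value <- wt$p.value
  }
  tibble::tibble(measure = measure, group1 = labels[1], group2 = labels[2],
                 n1 = length(x), n2 = length(y),
                 normality_p1 = p1, normality_p2 = p2,
                 test_used = test_used, statistic = statistic,
                 p_value = p_value, significant = p_value < alpha)
}

#' Batch group comparisons over a measure table
#'
#' @param measures Tibble with `genotype` and numeric measure columns.
#' @param alpha,normality_alpha See [compare_groups()].
#' @param reference Optional reference group label; defaults to the
#'   lexicographically first genotype.
#' @return Tibble of [compare_groups()] rows, one per measure, with a
#'   `note` column recording that no multiplicity correction was applied.
#' @export
compare_groups_table <- function(measures, alpha = 0.05,
                                 normality_alpha = 0.05,
                                 reference = NULL) {
  groups <- sort(unique(measures$genotype))
  if (length(groups) != 2) {
    abort("compare_groups_table() requires exactly two genotype groups.")
  }
  if (!is.null(reference)) {
    groups <- c(reference, setdiff(groups, reference))
  }
  cols <- setdiff(names(measures), c("animal_id", "genotype"))
  cols <- cols[vapply(measures[cols], is.numeric, logical(1))]
  out <- purrr::map_dfr(cols, function(cl) {
    x <- measures[[cl]][measures$genotype == groups[1]]
    y <- measures[[cl]][measures$genotype == groups[2]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) {
      return(tibble::tibble(measure = cl, group1 = groups[1],
                            group2 = groups[2], n1 = length(x),
                            n2 = length(y), normality_p1 = NA_real_,
                            normality_p2 = NA_real_,
                            test_used = NA_character_, statistic = NA_real_,
                            p_value = NA_real_, significant = NA))
    }
    compare_groups(x, y, alpha = alpha, normality_alpha = normality_alpha,
                   labels = groups, measure = cl)
  })
  out$note <- "no multiple-testing correction applied"
  out
}
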