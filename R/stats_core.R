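#' @title Elementary two-group and enrichment tests
#' @description Thin, contract-enforcing wrappers around base R's tests. They
#'   exist so every screening stage produces a uniform `test_result` record
#'   (statistic, two-tailed p, method tag, group sizes) and so degenerate
#'   small-sample inputs (constant vectors, complete ties) have defined
#'   behaviour instead of errors.
#' @name stats_core
NULL

test_result <- function(statistic, p_value, method, n_x, n_y, degenerate = FALSE) {
  structure(
    list(
      statistic = unname(statistic),
      p_value = unname(min(max(p_value, 0), 1)),
      method = method,
      n_x = n_x,
      n_y = n_y,
      degenerate = degenerate
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result %s> statistic = %.4g, p = %.4g (n = %d, %d)%s\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Two-sample t-test
#'
#' Unpaired two-tailed t-test, Student (pooled variance, the default) or
#' Welch. The statistic is signed as `mean(x) - mean(y)`. Zero-variance
#' inputs are handled explicitly: equal means give statistic 0 and p = 1;
#' unequal means with zero variance give p = 0, flagged degenerate.
#'
#' @param x,y Numeric vectors, each of length >= 2, finite values.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return A `test_result` with method `student_t` or `welch_t`.
#' @export
ttest_two_sample <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(x)), all(is.finite(y)))
  method <- if (variant == "student") "student_t" else "welch_t"
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(test_result(0, 1, method, length(x), length(y)))
    }
    return(test_result(sign(mean(x) - mean(y)) * Inf, 0, method,
                       length(x), length(y), degenerate = TRUE))
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "student"))
  test_result(fit$statistic, fit$p.value, method, length(x), length(y))
}

#' Mann-Whitney U test
#'
#' Two-tailed rank-sum test. The exact permutation null is used when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie correction (and continuity correction) is
#' used. The `method` field records which path was taken. The statistic is
#' the U count for `x` over `y`.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A `test_result` with method `mann_whitney_exact` or
#'   `mann_whitney_normal`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(test_result(length(x) * length(y) / 2, 1, "mann_whitney_normal",
                       length(x), length(y)))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= 20L) && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  test_result(fit$statistic, fit$p.value,
              if (exact) "mann_whitney_exact" else "mann_whitney_normal",
              length(x), length(y))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction. With all observations equal the statistic
#' is defined as 0 with p = 1 (the tie-corrected denominator vanishes).
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A `test_result` with method `kruskal_wallis`; `n_x` is the total
#'   sample size and `n_y` the number of groups.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(test_result(0, 1, "kruskal_wallis", length(pooled), length(groups)))
  }
  fit <- stats::kruskal.test(groups)
  test_result(fit$statistic, fit$p.value, "kruskal_wallis",
              length(pooled), length(groups))
}

#' Hypergeometric over-representation test
#'
#' Right-tail hypergeometric test of the overlap between a selected feature
#' set and a pathway within a common background: p = P(overlap >= observed)
#' when drawing `|selected|` features from the background. An empty selected
#' or pathway set gives p = 1.
#'
#' @param selected,pathway,background Character vectors of feature ids;
#'   `selected` and `pathway` must be subsets of `background`.
#' @return A `test_result` with method `hypergeometric`; the statistic is the
#'   observed overlap count, `n_x` = |selected|, `n_y` = |pathway|.
#' @export
hypergeometric_enrichment <- function(selected, pathway, background) {
  selected <- unique(selected); pathway <- unique(pathway)
  background <- unique(background)
  if (!all(selected %in% background)) stop("`selected` must be a subset of `background`")
  if (!all(pathway %in% background)) stop("`pathway` must be a subset of `background`")
  k <- length(intersect(selected, pathway))
  if (length(selected) == 0L || length(pathway) == 0L) {
    return(test_result(k, 1, "hypergeometric", length(selected), length(pathway)))
  }
  p <- stats::phyper(k - 1, length(pathway), length(background) - length(pathway),
                     length(selected), lower.tail = FALSE)
  test_result(k, p, "hypergeometric", length(selected), length(pathway))
}
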