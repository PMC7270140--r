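#' Pearson correlation with a t-based p-value
#'
#' The elementary statistic behind every edge in the cell-cytokine network
#' and every cytokine-module label. The two-sided p-value comes from the
#' classical transform t = r * sqrt((n - 2) / (1 - r^2)) with n - 2 degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return A one-row tibble with columns `rho`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero-variance vector", call. = FALSE)
  }
  rho <- stats::cor(x, y)
  # |rho| can exceed 1 by rounding; clamp before the t transform
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups with midrank tie handling. The exact
#' null distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. This is the location test applied to module
#' eigengenes (skull base vs convexity).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A one-row tibble with `U` (the statistic for group `a`) and the
#'   two-sided `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  pooled <- c(a, b)
  if (all(pooled == pooled[1])) {
    # every observation tied: no evidence of a shift in either direction
    return(tibble::tibble(U = unname(U), p = 1))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble::tibble(U = unname(U), p = min(1, wt$p.value))
}
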