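# Rank-sum comparison of per-animal dynamics. Group sizes in chronic
# imaging experiments are small (4-5 animals), too small to assume
# normality, so groups are compared with the Mann-Whitney U test: exact by
# enumeration for small samples, normal approximation with tie correction
# otherwise.

#' Mann-Whitney U test for two groups of per-animal values
#'
#' Two-sided rank-sum test. For `n1 + n2 <= 12` (the regime of typical
#' per-genotype animal counts) the p value is exact, computed by
#' enumerating all assignments of the pooled observed values to the two
#' groups, which honors ties; larger samples use the normal approximation
#' with midranks, tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors of per-animal values (each non-empty).
#' @param method `"auto"` (exact up to 12 total observations),
#'   `"exact"`, or `"approximate"`.
#' @param continuity Apply the continuity correction in the normal
#'   approximation.
#' @return An object of class `mann_whitney`: list with `u` (U statistic
#'   of the first group, in `[0, n1*n2]`), `p_value`, `n1`, `n2`,
#'   `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "approximate"),
                         continuity = TRUE) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "auto") method <- if (n <= 12L) "exact" else "approximate"
  if (method == "exact") {
    dev <- abs(u - mu)
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2L, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= dev - 1e-9)
  } else {
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- mu / 6 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- abs(u - mu)
      if (continuity) dev <- max(0, dev - 0.5)
      p <- min(1, 2 * stats::pnorm(-dev / sqrt(sigma2)))
    }
  }
  structure(list(u = u, p_value = p, n1 = n1, n2 = n2, method = method),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), %s p = %.4g\n",
              x$u, x$n1, x$n2, x$method, x$p_value))
  invisible(x)
}

#' Compare a per-animal metric between two groups
#'
#' Convenience wrapper pairing [group_summary()] with [mann_whitney()] for
#' a two-group design.
#'
#' @param values Numeric per-animal values.
#' @param group Two-level group label per animal.
#' @param ... Passed to [mann_whitney()].
#' @return List with `summary` (per-group mean/SEM/n) and `test`
#'   (`mann_whitney` result).
#' @export
group_compare <- function(values, group, ...) {
  lev <- unique(group)
  if (length(lev) != 2L)
    stop("`group` must have exactly two levels", call. = FALSE)
  list(summary = group_summary(values, group),
       test = mann_whitney(values[group == lev[1]],
                           values[group == lev[2]], ...))
}
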