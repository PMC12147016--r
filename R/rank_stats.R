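#' Two-sided Mann-Whitney U test
#'
#' The rank-sum comparison used by every stage of the package. The exact null
#' distribution is used when the pooled sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. The reported U statistic is the minimum of the two
#' one-sided statistics. Significance classes follow the usual star
#' convention: *** p < .001, ** p < .01, * p < .05, ns otherwise.
#'
#' @param a,b numeric samples (each nonempty).
#' @param alternative test sidedness; two-sided by default.
#' @return an object of class \code{"rank_test"}: list with u_statistic,
#'   p_value, n_a, n_b, mean_a, mean_b, method ("exact" or "normal_approx"),
#'   significance.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1)
    stop("mann_whitney_u requires both samples nonempty")
  n_a <- length(a); n_b <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (n_a + n_b) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  u_a <- unname(wt$statistic)       # number of (a, b) pairs with a > b
  # all pooled values identical: zero-variance degenerate case, no evidence
  p <- if (is.na(wt$p.value)) 1 else wt$p.value
  structure(list(
    u_statistic = min(u_a, n_a * n_b - u_a),
    p_value = p,
    n_a = n_a, n_b = n_b,
    mean_a = mean(a), mean_b = mean(b),
    method = if (exact) "exact" else "normal_approx",
    significance = significance_class(p)
  ), class = "rank_test")
}

#' Star code for a p-value
#'
#' @param p p-value(s).
#' @return "***" (p < .001), "**" (p < .01), "*" (p < .05) or "ns".
#' @export
significance_class <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U: U = %g, p = %.4g (%s, %s)  n = %d vs %d, means %.4g vs %.4g\n",
    x$u_statistic, x$p_value, x$method, x$significance,
    x$n_a, x$n_b, x$mean_a, x$mean_b))
  invisible(x)
}

# Flatten a rank_test (or NULL) into a one-row data.frame for result tables.
rank_test_row <- function(rt) {
  if (is.null(rt)) {
    return(data.frame(u_statistic = NA_real_, p_value = NA_real_,
                      n_a = NA_integer_, n_b = NA_integer_,
                      mean_a = NA_real_, mean_b = NA_real_,
                      significance = NA_character_,
                      stringsAsFactors = FALSE))
  }
  data.frame(u_statistic = rt$u_statistic, p_value = rt$p_value,
             n_a = rt$n_a, n_b = rt$n_b,
             mean_a = rt$mean_a, mean_b = rt$mean_b,
             significance = rt$significance, stringsAsFactors = FALSE)
}
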