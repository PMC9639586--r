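#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided Wilcoxon signed-rank test with the exact null
#' distribution for up to 25 untied non-zero pairs and the normal
#' approximation (with continuity correction) above; zero differences
#' are dropped, following the usual convention.
#'
#' @param x,y Paired numeric samples.
#' @return List with \code{statistic} (W, the positive-rank sum),
#'   \code{p_value} and \code{conf_int} (95% CI of the location shift).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                       correct = TRUE, conf.int = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       conf_int = unname(wt$conf.int))
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum test with tie correction, for unpaired samples.
#'
#' @param a,b Numeric samples.
#' @return List with \code{statistic} (U), \code{p_value} and
#'   \code{conf_int} (95% CI of the location shift).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  exact <- length(a) <= 25 && length(b) <= 25 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       conf.int = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       conf_int = unname(wt$conf.int))
}
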