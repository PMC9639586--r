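#' Upper-bound regression between trill bandwidth and trill rate
#'
#' Fits the performance frontier of the rate-bandwidth trade-off, pooling
#' songs of both sexes: the bandwidth axis is partitioned into bins
#' (100 Hz by default), the maximum trill rate within each non-empty bin
#' is taken, and an ordinary least-squares line is fitted through the
#' (bin centre, maximum rate) points. On biologically plausible data the
#' slope is negative: broader-band trills cannot be repeated as fast.
#'
#' @param bandwidth Numeric vector, song bandwidths in Hz.
#' @param rate Numeric vector, song trill rates in notes/s.
#' @param bin_width Bandwidth bin width in Hz.
#' @return An \code{upper_bound_model}: list with \code{slope},
#'   \code{intercept} (notes/s at 0 Hz), \code{r} (correlation of the
#'   bound fit), \code{df} (\code{n_bins - 2}) and the
#'   \code{bin_maxima} data frame.
#' @export
fit_upper_bound <- function(bandwidth, rate, bin_width = 100) {
  keep <- is.finite(bandwidth) & is.finite(rate)
  bandwidth <- bandwidth[keep]; rate <- rate[keep]
  if (length(bandwidth) == 0) stop("no usable (bandwidth, rate) points")
  bin <- floor(bandwidth / bin_width)
  # per-bin maximum rate; ties broken by first occurrence
  idx <- vapply(split(seq_along(rate), bin),
                function(i) i[which.max(rate[i])], 1L)
  centres <- (as.numeric(names(idx)) + 0.5) * bin_width
  maxima <- rate[idx]
  if (length(centres) < 3) {
    stop("degenerate upper-bound fit: fewer than 3 non-empty bins")
  }
  fit <- stats::lm(maxima ~ centres)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(centres, maxima),
    df = length(centres) - 2L,
    bin_width = bin_width,
    bin_maxima = data.frame(bandwidth = centres, max_rate = maxima)
  ), class = "upper_bound_model")
}

#' Vocal deviation from the upper-bound performance limit
#'
#' Orthogonal (perpendicular) distance of a song's (bandwidth, trill
#' rate) point to the fitted upper-bound line, signed positive below the
#' bound, i.e. larger values mean performance further from the limit.
#' Distances are computed in the fitting axes (Hz, notes/s); with the
#' shallow slopes typical of the frontier (|slope| << 1 notes/s per Hz)
#' the orthogonal distance is dominated by the rate shortfall.
#'
#' @param bandwidth Song bandwidth, Hz (vectorized).
#' @param rate Song trill rate, notes/s.
#' @param model An \code{upper_bound_model}.
#' @return Signed orthogonal distance(s); \code{NA} where either input
#'   is missing.
#' @export
vocal_deviation <- function(bandwidth, rate, model) {
  stopifnot(inherits(model, "upper_bound_model"))
  (model$intercept + model$slope * bandwidth - rate) /
    sqrt(1 + model$slope^2)
}
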