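#' Log-link binomial GLM of singing context
#'
#' Models the per-individual proportion of observations in each context
#' as a function of sex, context and their full interaction, with a
#' binomial likelihood and a log link, so exponentiated coefficients are
#' rate ratios. Reference levels are female and solo song. The binomial
#' totals (observations per individual) enter as weights; the data carry
#' one proportion per individual per context, so there are no repeated
#' measures and no random terms.
#'
#' Log-link binomial fits can step outside the parameter space; the fit
#' starts from the log weighted cell means and, on failure, retries from
#' a damped start before giving up.
#'
#' @param rows Output of [build_context_proportions()]: columns
#'   \code{individual}, \code{sex} ("F"/"M"), \code{context},
#'   \code{k}, \code{n}.
#' @return A \code{context_glm}: list with \code{coefficients} (data
#'   frame: term, log-scale estimate, CI and Z, plus back-transformed
#'   estimate and CI obtained by exponentiation), \code{r2_mcfadden}
#'   and the underlying \code{glm} object.
#' @export
fit_context_glm <- function(rows) {
  stopifnot(all(c("individual", "sex", "context", "k", "n") %in% names(rows)))
  d <- rows
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$context <- factor(d$context, levels = c("solo", "alarm", "agonistic"))

  # start values: log weighted cell means (the model is saturated in
  # the sex x context cells, so this is essentially the MLE)
  cell_p <- tapply(d$k, list(d$sex, d$context), sum) /
    tapply(d$n, list(d$sex, d$context), sum)
  cell_p <- pmin(pmax(cell_p, 1e-6), 1 - 1e-6)
  lp <- log(cell_p)
  start <- c(lp["F", "solo"],
             lp["F", "alarm"] - lp["F", "solo"],
             lp["F", "agonistic"] - lp["F", "solo"],
             lp["M", "solo"] - lp["F", "solo"],
             lp["M", "alarm"] - lp["M", "solo"] -
               (lp["F", "alarm"] - lp["F", "solo"]),
             lp["M", "agonistic"] - lp["M", "solo"] -
               (lp["F", "agonistic"] - lp["F", "solo"]))

  fit_once <- function(st) {
    suppressWarnings(stats::glm(
      cbind(k, n - k) ~ sex * context, data = d,
      family = stats::binomial(link = "log"), start = st
    ))
  }
  fit <- try(fit_once(start), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged) {
    fit2 <- try(fit_once(start * 0.5), silent = TRUE)  # damped retry
    if (inherits(fit2, "try-error") || !fit2$converged) {
      if (inherits(fit, "try-error")) {
        stop("log-link binomial GLM failed to converge")
      }
    } else {
      fit <- fit2
    }
  }

  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  if (any(!is.finite(se)) || any(abs(est) > 15) || any(se > 50)) {
    stop("context GLM estimate diverged (complete separation?)")
  }
  # profile-likelihood CIs (better calibrated than Wald when some
  # context counts are small); Wald fallback if profiling fails
  ci <- try(suppressWarnings(suppressMessages(
    stats::confint(fit, level = 0.95)
  )), silent = TRUE)
  if (inherits(ci, "try-error") || anyNA(ci)) {
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
  } else {
    lo <- ci[, 1]
    hi <- ci[, 2]
  }
  coefs <- data.frame(
    term = rownames(sm),
    estimate = unname(est), ci_lower = unname(lo), ci_upper = unname(hi),
    z = unname(est / se),
    back_estimate = unname(exp(est)),
    back_ci_lower = unname(exp(lo)), back_ci_upper = unname(exp(hi)),
    stringsAsFactors = FALSE
  )
  null_fit <- suppressWarnings(stats::glm(
    cbind(k, n - k) ~ 1, data = d,
    family = stats::binomial(link = "log"), start = lp["F", "solo"]
  ))
  r2 <- 1 - as.numeric(stats::logLik(fit)) / as.numeric(stats::logLik(null_fit))
  structure(list(coefficients = coefs, r2_mcfadden = r2, fit = fit),
            class = "context_glm")
}
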