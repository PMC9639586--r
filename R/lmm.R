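#' Scale and center a numeric variable
#'
#' Standardizes to mean 0, SD 1 so model estimates for continuous
#' predictors are comparable.
#'
#' @param x Numeric vector with positive SD.
#' @return Standardized vector.
#' @export
scale_center <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot scale a constant variable")
  (x - mean(x)) / s
}

#' Variance inflation factors of a fixed-effect design
#'
#' Computes the VIF of every non-interaction column of the design matrix
#' by its definition, \code{1 / (1 - R^2)} from the auxiliary regression
#' of that column on all other non-interaction columns. Columns arising
#' from interactions are excluded from the screen, since their
#' collinearity with their parent terms is structural. Multicollinearity
#' is flagged when VIF exceeds 3.
#'
#' @param formula Fixed-effects formula (right-hand side).
#' @param data Data frame.
#' @param threshold Flagging threshold.
#' @return Data frame \code{term}, \code{vif}, \code{flagged}.
#' @export
vif_screen <- function(formula, data, threshold = 3) {
  mm <- stats::model.matrix(formula, data)
  assign <- attr(mm, "assign")
  labs <- attr(stats::terms(formula, data = data), "term.labels")
  orders <- attr(stats::terms(formula, data = data), "order")
  keep_terms <- which(orders == 1)  # main effects only
  cols <- which(assign %in% keep_terms)
  if (length(cols) < 2) stop("need at least two non-interaction columns")
  X <- mm[, cols, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  data.frame(term = colnames(X), vif = vifs, flagged = vifs > threshold,
             stringsAsFactors = FALSE)
}

#' Small-sample Akaike information criterion
#'
#' \code{AICc = AIC + 2k(k+1)/(n - k - 1)} with \code{k} the number of
#' estimated parameters (from the log-likelihood df) and \code{n} the
#' number of observations.
#'
#' @param fit A fitted model with \code{logLik} and \code{nobs} methods.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a Gaussian linear mixed model for one song trait
#'
#' Maximum-likelihood fit (so AICc is comparable across fixed
#' structures) with Gaussian errors and identity link, and random
#' intercepts for individual and for pair, reflecting songs nested
#' within individual and within pair. A singular fit pins the affected
#' variance at zero, with lme4's message suppressed to a warning upstream.
#'
#' @param data Data frame of song-level rows.
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms (e.g.
#'   \code{c("sex", "age", "weeks", "sex:age")}); empty for an
#'   intercept-only model.
#' @param random Random-effects part of the formula.
#' @return List with the \code{lme4} \code{fit}, \code{aicc},
#'   \code{fixed_terms} and \code{varcomp} (data frame of variance and
#'   SD for individual, pair and residual).
#' @export
fit_lmm <- function(data, response, fixed_terms = character(0),
                    random = "(1 | individual) + (1 | pair)") {
  if (length(unique(data$individual)) < 2 || length(unique(data$pair)) < 2) {
    stop("need at least 2 individuals and 2 pairs")
  }
  rhs <- if (length(fixed_terms) == 0) "1"
         else paste(fixed_terms, collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs, "+", random))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = data, REML = FALSE,
               control = lme4::lmerControl(
                 calc.derivs = FALSE,
                 check.conv.singular = lme4::.makeCC(action = "ignore",
                                                     tol = 1e-4)))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- data.frame(
    term = vc$grp,
    variance = vc$vcov,
    sd = vc$sdcor,
    stringsAsFactors = FALSE
  )
  list(fit = fit, aicc = aicc(fit), fixed_terms = fixed_terms,
       varcomp = varcomp)
}
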