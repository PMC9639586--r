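#' Marginal and conditional R-squared of a Gaussian mixed model
#'
#' Variance-decomposition R-squared for mixed models: the marginal
#' \code{R2m} is the share of total variance explained by the fixed
#' effects alone, the conditional \code{R2c} the share explained by
#' fixed plus random effects. Total variance is the sum of the
#' fixed-effect variance (variance of the linear predictor), all random
#' intercept variances, and the residual variance.
#'
#' @param fit A \code{merMod} from [fit_lmm()] (Gaussian, identity link).
#' @return Named numeric vector \code{r2m}, \code{r2c}.
#' @export
r2_glmm <- function(fit) {
  if (is.list(fit) && !is.null(fit$fit)) fit <- fit$fit
  var_fixed <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  total <- var_fixed + var_rand + var_resid
  c(r2m = var_fixed / total, r2c = (var_fixed + var_rand) / total)
}

admissible_subsets <- function(full_terms) {
  mains <- full_terms[!grepl(":", full_terms, fixed = TRUE)]
  ints <- full_terms[grepl(":", full_terms, fixed = TRUE)]
  main_sets <- lapply(0:length(mains), function(k) {
    utils::combn(mains, k, simplify = FALSE)
  })
  main_sets <- unlist(main_sets, recursive = FALSE)
  out <- list()
  for (ms in main_sets) {
    ok_ints <- ints[vapply(strsplit(ints, ":", fixed = TRUE),
                           function(p) all(p %in% ms), FALSE)]
    int_sets <- unlist(lapply(0:length(ok_ints), function(k) {
      utils::combn(ok_ints, k, simplify = FALSE)
    }), recursive = FALSE)
    for (is_ in int_sets) {
      out[[length(out) + 1L]] <- full_terms[full_terms %in% c(ms, is_)]
    }
  }
  out
}

#' All-subsets AICc model selection with full-model averaging
#'
#' Fits every admissible fixed-effect subset of the full model
#' (interactions only enter together with their main effects), ranks the
#' candidates by AICc, selects all models within \code{delta} AICc of
#' the best, and computes the averaged model over the selected set.
#' Two averages are reported per coefficient, following the standard
#' multimodel-inference convention: the full average (Akaike weights
#' renormalized over the selection, substituting zero where a model
#' lacks the term -- a shrinkage point estimate) and the conditional
#' average (over the models that contain the term). Confidence
#' intervals and Z values come from the conditional average with the
#' unconditional standard error
#' (\code{sum w_i * sqrt(se_i^2 + (b_i - b_bar)^2)}), since the
#' zero-substituted full average is deliberately biased towards zero
#' and its spread does not form a usable interval. The relative
#' importance of a term is the summed weight of selected models
#' containing it. An effect is flagged significant when its 95% CI
#' excludes zero. R2m/R2c and the random-effect variances are reported
#' from the full model.
#'
#' @param data Song-level data frame.
#' @param response Response column name.
#' @param full_terms Character vector of fixed terms of the full model.
#' @param random Random-effects formula part.
#' @param delta AICc window for the selected set.
#' @param varcomp_ci One of \code{"none"} or \code{"profile"}: whether
#'   to add profile-likelihood 95% CIs for the random-effect SDs of the
#'   full model.
#' @return An \code{averaged_model}: list with \code{candidates} (term
#'   sets, AICc, delta, weights over all candidates), \code{selected}
#'   (indices), \code{coefficients} (averaged estimates, unconditional
#'   SE, CI, Z, significance flag), \code{importance},
#'   \code{varcomp}, \code{r2m}, \code{r2c}, and \code{full_fit}.
#' @export
all_subsets_average <- function(data, response, full_terms,
                                random = "(1 | individual) + (1 | pair)",
                                delta = 2, varcomp_ci = "none") {
  if (length(full_terms) > 20) {
    stop("refusing all-subsets search over more than 20 terms")
  }
  subsets <- admissible_subsets(full_terms)
  fits <- lapply(subsets, function(tt) {
    fit_lmm(data, response, tt, random = random)
  })
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  d_aicc <- aiccs - min(aiccs)
  w_all <- exp(-d_aicc / 2)
  w_all <- w_all / sum(w_all)
  sel <- which(d_aicc < delta)
  w_sel <- w_all[sel] / sum(w_all[sel])

  # union of coefficient names over the selected set
  coef_list <- lapply(fits[sel], function(m) lme4::fixef(m$fit))
  se_list <- lapply(fits[sel], function(m) {
    sqrt(diag(as.matrix(stats::vcov(m$fit))))
  })
  coef_names <- unique(unlist(lapply(coef_list, names)))
  rows <- lapply(coef_names, function(cn) {
    has <- vapply(coef_list, function(co) cn %in% names(co), FALSE)
    b <- vapply(coef_list, function(co) {
      if (cn %in% names(co)) co[[cn]] else 0
    }, numeric(1))
    s <- vapply(seq_along(coef_list), function(i) {
      if (has[i]) se_list[[i]][[cn]] else 0
    }, numeric(1))
    full <- sum(w_sel * b)
    w_c <- w_sel[has] / sum(w_sel[has])
    cond <- sum(w_c * b[has])
    se_c <- sum(w_c * sqrt(s[has]^2 + (b[has] - cond)^2))
    data.frame(coefficient = cn, estimate = full,
               estimate_conditional = cond, se = se_c,
               ci_lower = cond - 1.96 * se_c, ci_upper = cond + 1.96 * se_c,
               z = abs(cond) / se_c, stringsAsFactors = FALSE)
  })
  coefficients <- do.call(rbind, rows)
  coefficients$significant <- coefficients$ci_lower > 0 |
    coefficients$ci_upper < 0
  rownames(coefficients) <- NULL

  importance <- vapply(full_terms, function(tt) {
    sum(w_sel[vapply(fits[sel],
                     function(m) tt %in% m$fixed_terms, FALSE)])
  }, numeric(1))

  full_idx <- which(vapply(subsets, function(s) {
    length(s) == length(full_terms)
  }, FALSE))[1]
  full_fit <- fits[[full_idx]]
  r2 <- r2_glmm(full_fit$fit)
  varcomp <- full_fit$varcomp
  if (identical(varcomp_ci, "profile")) {
    ci <- try(suppressMessages(suppressWarnings(
      stats::confint(full_fit$fit, parm = "theta_", method = "profile",
                     quiet = TRUE)
    )), silent = TRUE)
    if (!inherits(ci, "try-error")) {
      # profile rows: .sig01, .sig02 (RE SDs in VarCorr order), .sigma
      varcomp$sd_ci_lower <- ci[, 1]
      varcomp$sd_ci_upper <- ci[, 2]
    }
  }

  structure(list(
    candidates = data.frame(
      terms = vapply(subsets, function(s) {
        if (length(s) == 0) "(intercept)" else paste(s, collapse = " + ")
      }, ""),
      aicc = aiccs, delta_aicc = d_aicc, weight = w_all,
      selected = seq_along(subsets) %in% sel,
      stringsAsFactors = FALSE
    ),
    selected = sel,
    coefficients = coefficients,
    importance = data.frame(term = full_terms,
                            importance = unname(importance),
                            stringsAsFactors = FALSE),
    varcomp = varcomp, r2m = unname(r2["r2m"]), r2c = unname(r2["r2c"]),
    full_fit = full_fit
  ), class = "averaged_model")
}
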