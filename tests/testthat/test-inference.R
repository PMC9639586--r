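# exhaustive null distribution of the signed-rank statistic
exact_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(pmin(2 * pmin(mean(w_all <= w_obs), mean(w_all >= w_obs)), 1))
}

# exhaustive pair-count U statistic
exact_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x < y) + 0.5 * (x == y)))
}

test_that("signed-rank test matches exhaustive enumeration at small n", {
  r <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$statistic, 0)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "all paired differences")

  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    x <- round(stats::runif(n, 0, 10), 2)
    y <- round(stats::runif(n, 0, 10), 2)
    if (any(duplicated(abs(x - y))) || any(x == y)) next
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p_value, exact_wilcoxon_p(x, y), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  r2 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(r2$statistic, 2)  # n^2/2 with full overlap

  set.seed(8)
  for (i in 1:10) {
    a <- stats::runif(sample(3:8, 1), 0, 10)
    b <- stats::runif(sample(3:8, 1), 0, 10)
    expect_equal(mann_whitney_u(b, a)$statistic, exact_u(a, b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("context GLM back-transforms by exponentiation with valid CIs", {
  pop <- synth_population(population_config(seed = 17))
  pr <- build_context_proportions(pop$observations)
  g <- fit_context_glm(pr)
  co <- g$coefficients
  expect_equal(co$back_estimate, exp(co$estimate), tolerance = 1e-12)
  expect_equal(co$back_ci_lower, exp(co$ci_lower), tolerance = 1e-12)
  expect_equal(co$back_ci_upper, exp(co$ci_upper), tolerance = 1e-12)
  expect_true(all(co$back_ci_lower < co$back_ci_upper))
  expect_setequal(co$term,
                  c("(Intercept)", "sexM", "contextalarm",
                    "contextagonistic", "sexM:contextalarm",
                    "sexM:contextagonistic"))
  expect_gt(g$r2_mcfadden, 0)

  # complete separation: a context never used by one sex
  sep <- pr
  sep$k[sep$sex == "F" & sep$context == "agonistic"] <- 0L
  expect_error(fit_context_glm(sep), "diverged|converge")
})

test_that("scale_center standardizes and is shift-invariant", {
  expect_equal(scale_center(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(10)
  x <- stats::rnorm(50, 100, 7)
  z <- scale_center(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(scale_center(x + 5), z, tolerance = 1e-12)
  expect_equal(z, (x - mean(x)) / stats::sd(x))
  expect_error(scale_center(rep(2, 5)), "constant")
})

test_that("VIF screen matches its definition and flags collinearity", {
  set.seed(11)
  n <- 120
  d <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  v <- vif_screen(~ a + b, d)
  expect_true(all(abs(v$vif[v$term != "(Intercept)"] - 1) < 0.15))
  expect_false(any(v$flagged[v$term != "(Intercept)"]))

  d$c <- d$a + stats::rnorm(n, 0, 0.01)
  v2 <- vif_screen(~ a + b + c, d)
  expect_true(v2$flagged[v2$term == "a"])
  expect_gt(v2$vif[v2$term == "a"], 3)

  # interactions excluded from the screen
  v3 <- vif_screen(~ a * b, d)
  expect_false("a:b" %in% v3$term)

  if (requireNamespace("car", quietly = TRUE)) {
    fit <- stats::lm(stats::rnorm(n) ~ a + b + c, data = d)
    ref <- car::vif(fit)
    got <- vif_screen(~ a + b + c, d)
    expect_equal(got$vif[match(names(ref), got$term)], unname(ref),
                 tolerance = 1e-6)
  }

  d$dup <- d$a
  expect_error(vif_screen(~ a + dup, d), "rank")
})

test_that("AICc equals the hand formula and LMMs recover variances", {
  pop <- synth_population(population_config(seed = 19))
  songs <- analysis_frame(pop)
  m <- fit_lmm(songs, "trill_length", "sex")
  ll <- stats::logLik(m$fit)
  k <- attr(ll, "df")
  n <- stats::nobs(m$fit)
  expect_equal(m$aicc,
               -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)
  expect_setequal(m$varcomp$term, c("individual", "pair", "Residual"))

  expect_error(fit_lmm(songs[songs$pair == "P01", ], "trill_length", "sex"),
               "at least 2")
})

test_that("zero-variance truths give near-zero random-effect estimates", {
  cfg <- population_config(seed = 23)
  cfg$traits$trill_length$var_ind <- 0
  cfg$traits$trill_length$var_pair <- 0
  pop <- synth_population(cfg)
  songs <- analysis_frame(pop)
  m <- fit_lmm(songs, "trill_length", "sex")
  re <- m$varcomp$variance[m$varcomp$term != "Residual"]
  expect_lt(sum(re), 0.002)
  # reduces to OLS: fixed estimates match lm closely
  ols <- stats::lm(trill_length ~ sex, data = songs)
  expect_equal(unname(lme4::fixef(m$fit)), unname(stats::coef(ols)),
               tolerance = 0.01)
})

test_that("peak-frequency variance components are recovered at scale", {
  # truth: individual 0.15, pair 0.02, residual 0.09 (kHz^2)
  reps <- lapply(1:6, function(r) {
    pop <- synth_population(population_config(seed = 600 + r))
    songs <- analysis_frame(pop)
    fit_lmm(songs, "peak_freq",
            c("sex", "age_c", "weeks_s", "sex:age_c",
              "sex:weeks_s"))$varcomp
  })
  est <- sapply(reps, function(v) v$variance[match(
    c("individual", "pair", "Residual"), v$term)])
  avg <- rowMeans(est)
  expect_lt(abs(avg[1] - 0.15), 0.075)
  expect_lt(abs(avg[2] - 0.02), 0.04)
  expect_lt(abs(avg[3] - 0.09), 0.02)
})

test_that("R2m/R2c decompose variance consistently", {
  pop <- synth_population(population_config(seed = 29))
  songs <- analysis_frame(pop)
  m <- fit_lmm(songs, "peak_freq", c("sex", "age_c", "weeks_s"))
  r2 <- r2_glmm(m)
  expect_true(r2[["r2m"]] <= r2[["r2c"]])
  expect_true(r2[["r2c"]] <= 1)
  # random share computed independently
  vc <- m$varcomp
  var_rand <- sum(vc$variance[vc$term != "Residual"])
  total <- stats::var(as.vector(stats::model.matrix(m$fit) %*%
                                  lme4::fixef(m$fit))) +
    sum(vc$variance)
  expect_equal(r2[["r2c"]] - r2[["r2m"]], var_rand / total,
               tolerance = 1e-9)

  # no fixed effects: marginal share is zero
  m0 <- fit_lmm(songs, "peak_freq", character(0))
  expect_equal(unname(r2_glmm(m0)["r2m"]), 0, tolerance = 1e-9)
})
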