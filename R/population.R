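#' Configuration of a synthetic study population
#'
#' Defines the generative truth for a seeded population of breeding
#' pairs: per-trait fixed effects (sex, age, season), variance components
#' for individual and pair random intercepts and residual noise, per-sex
#' context probabilities and song-output distributions, and repertoire
#' size distributions. The defaults emulate the published field
#' estimates for blue tits: e.g. a trill-length sex effect of 0.196 s on
#' a 0.483 s female intercept with variance components 0.06 (individual),
#' 0 (pair) and 0.04 (residual); a female vocal-consistency intercept of
#' 0.867; song output of 10.2 +/- 10.6 (females) vs 24.3 +/- 23.5
#' (males) songs per observation; weekly singing probabilities of 8.2%
#' vs 28.2% of boxes visited; and smaller female song-type repertoires.
#'
#' Trait models are in natural units (kHz, seconds, notes/s, score) with
#' seasonal slopes per week to first egg. Context probabilities must sum
#' to 1 per sex; the defaults honour the male:female solo rate ratio of
#' 2.4 and the sex-by-alarm interaction ratio of 0.12 on the log scale.
#'
#' @param n_pairs Number of breeding pairs (one female + one male each).
#' @param seed Integer seed fixing the entire dataset.
#' @param traits Named list of per-trait generative parameters; see the
#'   default for the expected structure (intercept, effects, variances).
#' @param context_probs_female,context_probs_male Named probabilities
#'   (solo, alarm, agonistic) summing to 1.
#' @param songs_per_obs_mean,songs_per_obs_sd Named per-sex (\code{F},
#'   \code{M}) mean and SD of songs per observation (negative binomial,
#'   truncated at 1).
#' @param singing_prob Named per-sex per-box-visit singing probability.
#' @param repertoire_probs_female,repertoire_probs_male Probabilities of
#'   repertoire sizes 1, 2, 3, ... per sex.
#' @param mean_songs_per_individual Mean acoustic-dataset songs per
#'   individual (negative binomial, truncated at 1).
#' @param n_weeks Number of sampling weeks for the song-output dataset.
#' @param mean_obs_per_individual Named per-sex (\code{F}, \code{M})
#'   mean number of context observations per bird (Poisson, truncated
#'   at 1); defaults match the field intensities of roughly 2.8
#'   observations per female and 3.7 per male.
#' @return A validated \code{population_config} list.
#' @export
population_config <- function(
    n_pairs = 30,
    seed = 1,
    traits = list(
      peak_freq = list(intercept = 5.02, sex = 0.025, age = -0.152,
                       weeks = -0.064, age_sex = -0.232, weeks_sex = 0.018,
                       tarsus = 0, var_ind = 0.15, var_pair = 0.02,
                       var_resid = 0.09),
      vocal_consistency = list(intercept = 0.867, sex = 0.024, age = 0,
                               weeks = 0.009, age_sex = 0, weeks_sex = 0,
                               var_ind = 0.002, var_pair = 0,
                               var_resid = 0.004),
      trill_length = list(intercept = 0.483, sex = 0.196, age = 0,
                          weeks = 0, age_sex = 0, weeks_sex = 0,
                          var_ind = 0.06, var_pair = 0, var_resid = 0.04),
      trill_rate = list(intercept = 8.582, sex = -0.075, age = 0.2,
                        weeks = 0, age_sex = -0.127, weeks_sex = 0,
                        var_ind = 2.9, var_pair = 0.48, var_resid = 1.2)
    ),
    context_probs_female = c(solo = 0.30, alarm = 0.30, agonistic = 0.40),
    context_probs_male = c(solo = 0.72, alarm = 0.0864, agonistic = 0.1936),
    songs_per_obs_mean = c(F = 10.2, M = 24.3),
    songs_per_obs_sd = c(F = 10.6, M = 23.5),
    singing_prob = c(F = 0.082, M = 0.282),
    repertoire_probs_female = c(0.65, 0.25, 0.10),
    repertoire_probs_male = c(0.10, 0.40, 0.35, 0.15),
    mean_songs_per_individual = 12.7,
    n_weeks = 29,
    mean_obs_per_individual = c(F = 2.8, M = 3.7)) {
  stopifnot(n_pairs >= 0, mean_songs_per_individual > 0)
  for (p in list(context_probs_female, context_probs_male)) {
    stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  }
  for (tr in traits) {
    stopifnot(tr$var_ind >= 0, tr$var_pair >= 0, tr$var_resid >= 0)
  }
  structure(list(
    n_pairs = as.integer(n_pairs), seed = as.integer(seed),
    traits = traits,
    context_probs_female = context_probs_female,
    context_probs_male = context_probs_male,
    songs_per_obs_mean = songs_per_obs_mean,
    songs_per_obs_sd = songs_per_obs_sd,
    singing_prob = singing_prob,
    repertoire_probs_female = repertoire_probs_female,
    repertoire_probs_male = repertoire_probs_male,
    mean_songs_per_individual = mean_songs_per_individual,
    n_weeks = as.integer(n_weeks),
    mean_obs_per_individual = mean_obs_per_individual
  ), class = "population_config")
}

rnbinom_trunc <- function(n, mu, sd) {
  v <- max(sd^2, mu * 1.01)
  size <- mu^2 / (v - mu)
  pmax(1L, stats::rnbinom(n, mu = mu, size = size))
}

trait_value <- function(tr, male, older, weeks, b_ind, b_pair, n) {
  tr$intercept + tr$sex * male + tr$age * older + tr$weeks * weeks +
    tr$age_sex * older * male + tr$weeks_sex * weeks * male +
    b_ind + b_pair + stats::rnorm(n, 0, sqrt(tr$var_resid))
}

#' Generate a synthetic study population
#'
#' Draws a complete seeded dataset with the statistical structure the
#' downstream analyses assume: an individual table (sex, age class,
#' pair, tarsus, first-egg date), a song-level acoustic trait table
#' (peak frequency, vocal consistency, trill length, trill rate,
#' bandwidth, with individual and pair random intercepts and residual
#' noise), a focal-observation table (context, songs per observation,
#' week), and a weekly box-visit table with singing detections. Trill
#' rate and bandwidth are negatively coupled so the pooled data show the
#' rate-bandwidth performance frontier. Identical configurations
#' (including the seed) reproduce the dataset exactly.
#'
#' @param config A [population_config()].
#' @param render_audio Also render each song's waveform and label track?
#'   (Only sensible for small populations.)
#' @param out_dir Directory for WAV and label files when
#'   \code{render_audio = TRUE}.
#' @param sample_rate Sampling rate for rendered audio, Hz.
#' @return A list of data frames: \code{individuals}, \code{songs},
#'   \code{observations}, \code{box_visits} (and, when rendering,
#'   \code{audio_files}).
#' @export
synth_population <- function(config, render_audio = FALSE, out_dir = NULL,
                             sample_rate = 48000) {
  stopifnot(inherits(config, "population_config"))
  if (config$n_pairs == 0) stop("empty population: n_pairs = 0")
  set.seed(config$seed)

  n_ind <- 2L * config$n_pairs
  pair_id <- sprintf("P%02d", rep(seq_len(config$n_pairs), each = 2))
  sex <- rep(c("F", "M"), config$n_pairs)
  ind_id <- sprintf("%s%02d", sex, rep(seq_len(config$n_pairs), each = 2))
  age <- sample(c("yearling", "older"), n_ind, replace = TRUE,
                prob = c(0.4, 0.6))
  tarsus <- round(stats::rnorm(n_ind, 16.5 + 0.3 * (sex == "M"), 0.45), 1)
  # clutches start around late April (population mean first egg)
  egg_jd <- round(stats::rnorm(config$n_pairs, 112, 4))
  first_egg <- as.Date(egg_jd - 1, origin = "2019-01-01")
  individuals <- data.frame(
    individual = ind_id, sex = sex, age = age, pair = pair_id,
    tarsus_mm = tarsus,
    first_egg_date = rep(as.character(first_egg), each = 2),
    stringsAsFactors = FALSE
  )

  # repertoires drawn from a shared population pool of song types
  pool <- LETTERS[1:8]
  rep_size <- integer(n_ind)
  repertoire <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    probs <- if (sex[i] == "F") config$repertoire_probs_female
             else config$repertoire_probs_male
    rep_size[i] <- sample.int(length(probs), 1, prob = probs)
    repertoire[[i]] <- sample(pool, rep_size[i])
  }
  individuals$repertoire_size <- rep_size

  # song-level acoustic trait table
  n_songs <- rnbinom_trunc(n_ind, config$mean_songs_per_individual,
                           config$mean_songs_per_individual)
  b_ind <- lapply(config$traits, function(tr) {
    stats::rnorm(n_ind, 0, sqrt(tr$var_ind))
  })
  b_pair <- lapply(config$traits, function(tr) {
    rep(stats::rnorm(config$n_pairs, 0, sqrt(tr$var_pair)), each = 2)
  })
  rows <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    m <- n_songs[i]
    jd <- sort(sample(25:125, m, replace = TRUE))
    weeks <- as.integer(round((jd - egg_jd[ceiling(i / 2)]) / 7))
    male <- as.numeric(sex[i] == "M")
    older <- as.numeric(age[i] == "older")
    vals <- lapply(names(config$traits), function(nm) {
      trait_value(config$traits[[nm]], male, older, weeks,
                  b_ind[[nm]][i], b_pair[[nm]][i], m)
    })
    names(vals) <- names(config$traits)
    # the table carries the raw Gaussian model truth; physical clamps
    # (positive durations, consistency <= 1) apply only when rendering
    # rate-bandwidth trade-off: faster trills sweep narrower bands
    bw <- 4500 - 300 * (vals$trill_rate - 8.582) + stats::rnorm(m, 0, 350)
    bw <- pmin(pmax(bw, 800), 8000)
    rows[[i]] <- data.frame(
      individual = ind_id[i], sex = sex[i], age = age[i],
      pair = pair_id[i], tarsus_mm = tarsus[i],
      date = as.character(as.Date(jd - 1, origin = "2019-01-01")),
      julian = jd, weeks_to_egg = weeks,
      song_type = sample(repertoire[[i]], m, replace = TRUE),
      peak_freq = vals$peak_freq,
      vocal_consistency = vals$vocal_consistency,
      trill_length = vals$trill_length,
      trill_rate = vals$trill_rate,
      bandwidth = bw / 1000,
      stringsAsFactors = FALSE
    )
  }
  songs <- do.call(rbind, rows)
  rownames(songs) <- NULL

  # focal observations for the context and song-output datasets
  mo <- config$mean_obs_per_individual
  if (length(mo) == 1) mo <- c(F = unname(mo), M = unname(mo))
  n_obs <- pmax(1L, stats::rpois(n_ind, unname(mo[sex])))
  obs_rows <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    p <- if (sex[i] == "F") config$context_probs_female
         else config$context_probs_male
    ctx <- sample(names(p), n_obs[i], replace = TRUE, prob = p)
    wk <- sample.int(config$n_weeks, n_obs[i], replace = TRUE)
    ns <- rnbinom_trunc(n_obs[i],
                        config$songs_per_obs_mean[[sex[i]]],
                        config$songs_per_obs_sd[[sex[i]]])
    obs_rows[[i]] <- data.frame(
      individual = ind_id[i], sex = sex[i], pair = pair_id[i],
      context = ctx, week = wk, n_songs = as.integer(ns),
      stringsAsFactors = FALSE
    )
  }
  observations <- do.call(rbind, obs_rows)
  rownames(observations) <- NULL

  # weekly box visits with per-sex singing detections
  visits <- sample(20:40, config$n_weeks, replace = TRUE)
  box_visits <- data.frame(
    week = seq_len(config$n_weeks), n_visited = visits,
    f_singing = stats::rbinom(config$n_weeks, visits,
                              config$singing_prob[["F"]]),
    m_singing = stats::rbinom(config$n_weeks, visits,
                              config$singing_prob[["M"]])
  )

  out <- list(individuals = individuals, songs = songs,
              observations = observations, box_visits = box_visits)

  if (render_audio) {
    if (is.null(out_dir)) stop("out_dir required when rendering audio")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(nrow(songs))
    for (k in seq_len(nrow(songs))) {
      r <- songs[k, ]
      rate <- min(max(r$trill_rate, 3), 20)
      len <- max(r$trill_length, 2.5 / rate)
      dur <- min(0.06, 1 / rate - 0.015)
      n_tr <- max(3L, as.integer(round(rate * len)) + 1L)
      spec <- song_spec(
        n_intro_notes = 2, n_trill_notes = n_tr,
        trill_rate_true = rate, note_duration = dur,
        peak_freq_true = max(r$peak_freq, 2) * 1000,
        bandwidth_true = min(r$bandwidth * 1000,
                             2 * (max(r$peak_freq, 2) * 1000) - 400),
        consistency_jitter = max(0, 1 - min(r$vocal_consistency, 1)) * 0.3,
        song_type_id = r$song_type
      )
      sg <- synth_song(spec, sample_rate)
      base <- file.path(out_dir, sprintf("song_%04d_%s", k, r$individual))
      write_wav(sg$waveform, sample_rate, paste0(base, ".wav"))
      write_label_track(sg$labels, paste0(base, ".txt"))
      files[k] <- base
    }
    out$audio_files <- files
  }
  out
}
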