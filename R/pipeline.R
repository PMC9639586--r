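#' Run the full synthetic song analysis pipeline
#'
#' Orchestrates generate -> render/extract -> assemble -> analyze:
#' draws a seeded population, optionally renders a few songs to WAV +
#' label tracks and re-measures them from the audio (a self-check that
#' the measurement chain recovers the generative truth), assembles the
#' four analysis datasets (song output, context proportions, repertoire
#' pairs, acoustic traits with the vocal-deviation column), and runs the
#' statistical stage: Wilcoxon/Mann-Whitney sex comparisons, the
#' log-link binomial context GLM, and the five AICc-averaged mixed
#' models. Identical configurations reproduce the summary exactly.
#'
#' @param config A [population_config()].
#' @param out_dir Output directory for tables (and audio); \code{NULL}
#'   returns results without writing.
#' @param n_render Number of songs to render to audio and re-measure
#'   (0 skips the audio stage).
#' @param figures Write summary figures (requires ggplot2)?
#' @param varcomp_ci Passed to [all_subsets_average()].
#' @return A list: \code{data} (generated tables),
#'   \code{song_output} (weekly singing test + songs-per-observation
#'   test), \code{context} (GLM fit), \code{repertoire} (pairwise
#'   comparison + signed-rank test), \code{acoustic} (upper-bound model
#'   + one \code{averaged_model} per trait), and, when rendering,
#'   \code{measurement_check} (true vs re-measured features).
#' @export
run_pipeline <- function(config = population_config(), out_dir = NULL,
                         n_render = 0, figures = FALSE,
                         varcomp_ci = "none") {
  pop <- synth_population(config)
  res <- list(data = pop)

  # --- song output ---------------------------------------------------
  bv <- pop$box_visits
  weekly <- data.frame(week = bv$week,
                       f = bv$f_singing / bv$n_visited,
                       m = bv$m_singing / bv$n_visited)
  spo <- songs_per_observation(pop$observations)
  res$song_output <- list(
    weekly = weekly,
    weekly_test = wilcoxon_signed_rank(weekly$f, weekly$m),
    songs_female = spo$female, songs_male = spo$male,
    output_test = mann_whitney_u(spo$female, spo$male)
  )

  # --- behavioral context --------------------------------------------
  props <- build_context_proportions(pop$observations)
  res$context <- list(proportions = props, glm = fit_context_glm(props))

  # --- repertoire ----------------------------------------------------
  pairs <- unique(pop$individuals$pair)
  rep_rows <- list()
  for (p in pairs) {
    f_id <- pop$individuals$individual[pop$individuals$pair == p &
                                         pop$individuals$sex == "F"]
    m_id <- pop$individuals$individual[pop$individuals$pair == p &
                                         pop$individuals$sex == "M"]
    fs <- pop$songs[pop$songs$individual == f_id,
                    c("date", "song_type"), drop = FALSE]
    ms <- pop$songs[pop$songs$individual == m_id,
                    c("date", "song_type"), drop = FALSE]
    mp <- try(match_repertoire_pair(fs, ms), silent = TRUE)
    if (inherits(mp, "try-error")) next  # female below sampling threshold
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      pair = p, female = f_id, male = m_id,
      female_repertoire = mp$female_repertoire,
      male_repertoire = mp$male_repertoire, stringsAsFactors = FALSE
    )
  }
  rep_tab <- do.call(rbind, rep_rows)
  res$repertoire <- list(table = rep_tab)
  if (!is.null(rep_tab) && nrow(rep_tab) >= 3 &&
      any(rep_tab$female_repertoire != rep_tab$male_repertoire)) {
    res$repertoire$test <- wilcoxon_signed_rank(rep_tab$female_repertoire,
                                                rep_tab$male_repertoire)
  }

  # --- acoustic structure --------------------------------------------
  songs <- pop$songs
  ub <- fit_upper_bound(songs$bandwidth * 1000, songs$trill_rate)
  songs$vocal_deviation <- vocal_deviation(songs$bandwidth * 1000,
                                           songs$trill_rate, ub)
  songs$weeks_s <- scale_center(songs$weeks_to_egg)
  songs$tarsus_s <- scale_center(songs$tarsus_mm)
  songs$sex <- factor(songs$sex, levels = c("F", "M"))
  # age enters as a centred dummy so that, in models containing the
  # sex:age interaction, the sex coefficient keeps its meaning as the
  # average sex effect and can be averaged across models
  songs$age_c <- as.numeric(songs$age == "older")
  songs$age_c <- songs$age_c - mean(songs$age_c)

  base_terms <- c("sex", "age_c", "weeks_s", "sex:age_c", "sex:weeks_s")
  trait_terms <- list(
    peak_freq = c(base_terms, "tarsus_s", "sex:tarsus_s"),
    vocal_consistency = base_terms,
    trill_length = base_terms,
    trill_rate = base_terms,
    vocal_deviation = base_terms
  )
  res$acoustic <- list(upper_bound = ub, songs = songs)
  for (tr in names(trait_terms)) {
    res$acoustic[[tr]] <- all_subsets_average(
      songs, tr, trait_terms[[tr]], varcomp_ci = varcomp_ci
    )
  }

  # --- optional audio rendering + re-measurement ---------------------
  if (n_render > 0) {
    audio_dir <- file.path(out_dir %||% tempdir(), "audio")
    small <- config
    small$n_pairs <- 1L
    small$mean_songs_per_individual <- n_render
    rendered <- synth_population(small, render_audio = TRUE,
                                 out_dir = audio_dir)
    checks <- list()
    for (k in seq_along(rendered$audio_files)) {
      base <- rendered$audio_files[k]
      wav <- read_wav(paste0(base, ".wav"))
      lab <- read_label_track(paste0(base, ".txt"))
      notes <- cut_and_normalize_notes(wav$samples, lab, wav$sample_rate)
      s <- song(notes, n_intro = sum(lab$label == "i"))
      meas <- measure_song(s, wav$sample_rate)
      truth <- rendered$songs[k, ]
      checks[[k]] <- data.frame(
        song = basename(base),
        true_trill_rate = truth$trill_rate,
        measured_trill_rate = meas$trill_rate,
        true_trill_length = truth$trill_length,
        measured_trill_length = meas$trill_length,
        measured_consistency = meas$vocal_consistency,
        measured_peak_freq = meas$peak_freq,
        stringsAsFactors = FALSE
      )
    }
    res$measurement_check <- do.call(rbind, checks)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv <- function(x, name) {
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    write_tsv(pop$individuals, "individuals.tsv")
    write_tsv(songs, "songs_features.tsv")
    write_tsv(pop$observations, "observations.tsv")
    write_tsv(props, "context_proportions.tsv")
    write_tsv(res$context$glm$coefficients, "context_glm.tsv")
    if (!is.null(rep_tab)) write_tsv(rep_tab, "repertoire_pairs.tsv")
    for (tr in names(trait_terms)) {
      write_tsv(res$acoustic[[tr]]$coefficients,
                paste0("lmm_", tr, "_coefficients.tsv"))
      write_tsv(res$acoustic[[tr]]$candidates,
                paste0("lmm_", tr, "_candidates.tsv"))
    }
    if (figures) pipeline_figures(res, out_dir)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary figures for a pipeline run
#'
#' Boxplots of song output and acoustic traits by sex, and the fitted
#' seasonal trend in peak frequency. Requires ggplot2.
#'
#' @param res A [run_pipeline()] result.
#' @param out_dir Directory for PNG files.
#' @return Paths of the written files, invisibly.
#' @export
pipeline_figures <- function(res, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for figures")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  gg <- ggplot2::ggplot

  out <- data.frame(
    sex = rep(c("F", "M"), c(length(res$song_output$songs_female),
                             length(res$song_output$songs_male))),
    n_songs = c(res$song_output$songs_female, res$song_output$songs_male)
  )
  p1 <- gg(out, ggplot2::aes(x = sex, y = n_songs)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "songs per observation", x = NULL)
  f1 <- file.path(out_dir, "song_output.png")
  ggplot2::ggsave(f1, p1, width = 4, height = 4, dpi = 120)
  paths <- c(paths, f1)

  songs <- res$acoustic$songs
  long <- stats::reshape(
    songs[, c("sex", "peak_freq", "vocal_consistency", "trill_length",
              "trill_rate", "vocal_deviation")],
    direction = "long",
    varying = list(2:6),
    times = c("peak_freq", "vocal_consistency", "trill_length",
              "trill_rate", "vocal_deviation"),
    v.names = "value", timevar = "trait"
  )
  p2 <- gg(long, ggplot2::aes(x = sex, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
  f2 <- file.path(out_dir, "acoustic_traits.png")
  ggplot2::ggsave(f2, p2, width = 7, height = 5, dpi = 120)
  paths <- c(paths, f2)

  p3 <- gg(songs, ggplot2::aes(x = weeks_to_egg, y = peak_freq,
                               colour = sex)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(x = "weeks to first egg", y = "peak frequency (kHz)")
  f3 <- file.path(out_dir, "seasonal_peak_freq.png")
  ggplot2::ggsave(f3, p3, width = 5, height = 4, dpi = 120)
  paths <- c(paths, f3)
  invisible(paths)
}
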