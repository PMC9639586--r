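#' Julian date (day of year)
#'
#' Day-of-year with the first of January as origin (Jan 1 = 1), making
#' recording dates comparable across years.
#'
#' @param date A \code{Date} or ISO-8601 string.
#' @return Integer day of year.
#' @export
julian_date <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(d)) stop("invalid date: ", paste(date, collapse = ", "))
  as.integer(strftime(d, "%j"))
}

#' Weeks relative to the first egg date
#'
#' Integer week offset of a recording relative to the clutch's first egg
#' (week of first egg = 0, negative before laying). When no nest data
#' exist for the bird, the population mean first-egg date for that year
#' is used as fallback.
#'
#' @param recording_date Date (or string) of the recording.
#' @param first_egg_date Date of the first egg for that bird's nest, or
#'   \code{NA} to use the fallback.
#' @param population_mean_egg Fallback first-egg date (e.g. the
#'   population mean for that year); required when
#'   \code{first_egg_date} is \code{NA}.
#' @return Signed integer weeks.
#' @export
weeks_to_first_egg <- function(recording_date, first_egg_date = NA,
                               population_mean_egg = NULL) {
  egg <- first_egg_date
  if (is.na(egg)) {
    if (is.null(population_mean_egg)) {
      stop("no first-egg date and no population mean supplied")
    }
    egg <- population_mean_egg
  }
  as.integer(round((julian_date(recording_date) - julian_date(egg)) / 7))
}

#' Per-week singing probability by sex
#'
#' Proportion of nest-box visits at which a singing bird of each sex was
#' recorded, per week: singing detections / boxes visited. Weeks with
#' zero visits are excluded with a message.
#'
#' @param observations Data frame with columns \code{week} and
#'   \code{sex} (one row per singing detection).
#' @param box_visits Data frame with columns \code{week} and
#'   \code{n_visited}.
#' @return Data frame \code{week}, \code{sex}, \code{n_singing},
#'   \code{n_visited}, \code{proportion}; one row per week x sex, weeks
#'   taken from \code{box_visits}.
#' @export
singing_probability_per_week <- function(observations, box_visits) {
  stopifnot(all(c("week", "n_visited") %in% names(box_visits)))
  zero <- box_visits$n_visited <= 0
  if (any(zero)) {
    message("excluding ", sum(zero), " week(s) with zero box visits")
    box_visits <- box_visits[!zero, , drop = FALSE]
  }
  sexes <- c("F", "M")
  out <- expand.grid(week = box_visits$week, sex = sexes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_visited <- box_visits$n_visited[match(out$week, box_visits$week)]
  out$n_singing <- mapply(function(w, s) {
    sum(observations$week == w & observations$sex == s)
  }, out$week, out$sex)
  out$proportion <- out$n_singing / out$n_visited
  out[order(out$week, out$sex),
      c("week", "sex", "n_singing", "n_visited", "proportion")]
}

#' Songs per observation, split by sex
#'
#' Unpaired per-observation song counts for the female/male song-output
#' comparison (Mann-Whitney U). Dawn and unknown contexts are excluded.
#'
#' @param observations Data frame with columns \code{sex},
#'   \code{context}, \code{n_songs}.
#' @return List with numeric vectors \code{female} and \code{male}.
#' @export
songs_per_observation <- function(observations) {
  keep <- !(observations$context %in% c("dawn", "unknown"))
  obs <- observations[keep, , drop = FALSE]
  out <- list(female = obs$n_songs[obs$sex == "F"],
              male = obs$n_songs[obs$sex == "M"])
  if (length(out$female) == 0 || length(out$male) == 0) {
    stop("empty sex stratum in songs-per-observation data")
  }
  out
}

#' Per-individual context proportions
#'
#' For every individual, the proportion of observations in each daytime
#' singing context (solo, alarm, agonistic) relative to that
#' individual's total, adding zeroes for contexts never observed. Dawn
#' and unknown contexts are removed first; individuals with no usable
#' observation are excluded with a message. The result has exactly three
#' rows per retained individual.
#'
#' @param observations Data frame with columns \code{individual},
#'   \code{sex}, \code{context}.
#' @return Data frame \code{individual}, \code{sex}, \code{context},
#'   \code{k} (observations in context), \code{n} (individual total),
#'   \code{proportion}.
#' @export
build_context_proportions <- function(observations) {
  contexts <- c("solo", "alarm", "agonistic")
  obs <- observations[observations$context %in% contexts, , drop = FALSE]
  dropped <- setdiff(unique(observations$individual), unique(obs$individual))
  if (length(dropped) > 0) {
    message("excluding ", length(dropped),
            " individual(s) with no usable observation")
  }
  if (nrow(obs) == 0) stop("no usable observations")
  ids <- unique(obs$individual)
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- obs[obs$individual == id, , drop = FALSE]
    k <- vapply(contexts, function(cx) sum(sub$context == cx), 1L)
    data.frame(individual = id, sex = sub$sex[1], context = contexts,
               k = unname(k), n = nrow(sub),
               proportion = unname(k) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Date-matched repertoire comparison within a pair
#'
#' For each female recording date, selects the male recording date with
#' the nearest Julian date (regardless of year; ties go to the earlier
#' date), then takes the same number of songs from the matched male
#' recording as the female recording holds, counting from the first song
#' recorded -- unless the male recording has fewer songs, in which case
#' both sides are truncated to the male count. Repertoire size is the
#' number of distinct song-type labels across each bird's matched songs.
#'
#' @param female_songs Data frame with columns \code{date} and
#'   \code{song_type}, rows in recording order.
#' @param male_songs Same structure for the male partner.
#' @return A list: \code{matches} (data frame of matched dates and song
#'   counts used), \code{female_repertoire}, \code{male_repertoire},
#'   \code{female_types}, \code{male_types}.
#' @export
match_repertoire_pair <- function(female_songs, male_songs) {
  if (nrow(male_songs) == 0) stop("male partner has no recordings")
  f_dates <- unique(female_songs$date)
  if (length(f_dates) < 2) {
    stop("female must be recorded on two or more dates")
  }
  if (nrow(female_songs) <= 10) {
    stop("female must have more than 10 songs recorded overall")
  }
  m_dates <- unique(male_songs$date)
  m_jul <- julian_date(m_dates)

  f_used <- character(0); m_used <- character(0)
  rows <- vector("list", length(f_dates))
  for (i in seq_along(f_dates)) {
    fj <- julian_date(f_dates[i])
    dist <- abs(m_jul - fj)
    # nearest Julian date; ties broken towards the earlier male date
    cand <- which(dist == min(dist))
    md <- m_dates[cand[order(as.Date(m_dates[cand]))[1]]]
    f_block <- female_songs[female_songs$date == f_dates[i], , drop = FALSE]
    m_block <- male_songs[male_songs$date == md, , drop = FALSE]
    # male side matched to the female count, starting from the first
    # recorded song, unless the male recording holds fewer songs; the
    # female side is never truncated
    n_male <- min(nrow(f_block), nrow(m_block))
    f_used <- c(f_used, f_block$song_type)
    m_used <- c(m_used, m_block$song_type[seq_len(n_male)])
    rows[[i]] <- data.frame(female_date = f_dates[i], male_date = md,
                            n_female_songs = nrow(f_block),
                            n_male_songs = n_male,
                            stringsAsFactors = FALSE)
  }
  list(matches = do.call(rbind, rows),
       female_repertoire = length(unique(f_used)),
       male_repertoire = length(unique(m_used)),
       female_types = sort(unique(f_used)),
       male_types = sort(unique(m_used)))
}
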