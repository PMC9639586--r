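#' Measure all trill features of one song
#'
#' Computes every acoustic measurement on the trill of a song: note-level
#' spectral descriptors (peak, maximum and minimum frequency, bandwidth)
#' averaged into one value per song, and the performance metrics trill
#' length, trill rate and vocal consistency. Masked notes are excluded
#' from all measures; trill rate uses the longest unmasked run of
#' consecutive notes and is \code{NA} below three notes, as is vocal
#' consistency below two.
#'
#' @param s A \code{song}.
#' @param sample_rate Sampling rate, Hz.
#' @return One-row data frame: \code{peak_freq}, \code{max_freq},
#'   \code{min_freq}, \code{bandwidth} (kHz), \code{trill_length} (s),
#'   \code{trill_rate} (notes/s), \code{vocal_consistency},
#'   \code{n_notes_used}.
#' @export
measure_song <- function(s, sample_rate = 48000) {
  stopifnot(inherits(s, "song"))
  usable <- trill_notes(s, usable_only = TRUE)
  if (length(usable) == 0) {
    return(data.frame(peak_freq = NA_real_, max_freq = NA_real_,
                      min_freq = NA_real_, bandwidth = NA_real_,
                      trill_length = NA_real_, trill_rate = NA_real_,
                      vocal_consistency = NA_real_, n_notes_used = 0L))
  }
  specs <- lapply(usable, mean_power_spectrum, sample_rate = sample_rate)
  peaks <- vapply(specs, peak_frequency, numeric(1))
  ext <- t(vapply(specs, freq_extent, numeric(3)))
  data.frame(
    peak_freq = mean(peaks) / 1000,
    max_freq = mean(ext[, "max_freq"]) / 1000,
    min_freq = mean(ext[, "min_freq"]) / 1000,
    bandwidth = mean(ext[, "bandwidth"]) / 1000,
    trill_length = trill_length(usable),
    trill_rate = trill_rate(longest_unmasked_run(s)),
    vocal_consistency = vocal_consistency(usable, sample_rate),
    n_notes_used = length(usable)
  )
}

#' Song-level feature table with the per-type, per-date cap
#'
#' Measures every song and assembles one row per song, applying a cap of
#' at most \code{cap} songs per individual, song type and recording date
#' before measurement. The cap keeps the earliest-recorded songs (input
#' order within a group is taken as recording order). When enough songs
#' carry both bandwidth and trill rate, the pooled upper-bound regression
#' is fitted across both sexes and a \code{vocal_deviation} column added.
#'
#' @param songs List of \code{song} objects.
#' @param sample_rate Sampling rate, Hz.
#' @param cap Maximum songs per (individual, song type, date).
#' @param deviation Fit the upper bound and add vocal deviation?
#' @return Data frame, one row per retained song: metadata columns
#'   (\code{individual}, \code{sex}, \code{pair}, \code{date},
#'   \code{song_type}) plus all feature columns; attribute
#'   \code{upper_bound} holds the fitted model when computed.
#' @export
song_feature_table <- function(songs, sample_rate = 48000, cap = 10,
                               deviation = TRUE) {
  stopifnot(length(songs) > 0)
  key <- vapply(songs, function(s) {
    paste(s$individual, s$song_type, as.character(s$date), sep = "\r")
  }, "")
  seq_in_group <- stats::ave(seq_along(songs), key, FUN = seq_along)
  keep <- seq_in_group <= cap
  songs <- songs[keep]

  meta <- do.call(rbind, lapply(songs, function(s) {
    data.frame(individual = s$individual, sex = s$sex, pair = s$pair,
               date = as.character(s$date), song_type = s$song_type,
               stringsAsFactors = FALSE)
  }))
  feats <- do.call(rbind, lapply(songs, measure_song,
                                 sample_rate = sample_rate))
  tab <- cbind(meta, feats)
  if (any(tab$n_notes_used == 0)) {
    message("excluding ", sum(tab$n_notes_used == 0),
            " song(s) with no usable trill note")
    tab <- tab[tab$n_notes_used > 0, , drop = FALSE]
    rownames(tab) <- NULL
  }

  if (deviation) {
    ok <- is.finite(tab$bandwidth) & is.finite(tab$trill_rate)
    if (sum(ok) >= 3) {
      ub <- try(fit_upper_bound(tab$bandwidth[ok] * 1000,
                                tab$trill_rate[ok]), silent = TRUE)
      if (!inherits(ub, "try-error")) {
        tab$vocal_deviation <- vocal_deviation(tab$bandwidth * 1000,
                                               tab$trill_rate, ub)
        attr(tab, "upper_bound") <- ub
      } else {
        tab$vocal_deviation <- NA_real_
      }
    } else {
      tab$vocal_deviation <- NA_real_
    }
  }
  tab
}
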