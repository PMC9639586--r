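#' Cut labelled notes out of a recording and peak-normalize them
#'
#' Each label interval \code{[start, end)} is sliced out of the waveform
#' and scaled so its maximum absolute sample is 1. Peak normalization
#' keeps the downstream measures scale-free: both the spectrogram
#' cross-correlation and the -20 dB bandwidth threshold are relative
#' measures.
#'
#' @param waveform Numeric vector of samples.
#' @param labels Data frame with \code{start}, \code{end} (seconds) and
#'   optionally \code{label}.
#' @param sample_rate Sampling rate, Hz.
#' @param lenient If \code{FALSE} (default) a labelled interval with zero
#'   signal energy is an error; if \code{TRUE} it is kept and flagged
#'   \code{masked}.
#' @return A list of \code{note_segment} objects: lists with
#'   \code{start}, \code{end}, \code{label}, \code{samples} (peak
#'   amplitude 1) and \code{masked} (logical).
#' @export
cut_and_normalize_notes <- function(waveform, labels, sample_rate,
                                    lenient = FALSE) {
  dur <- length(waveform) / sample_rate
  if (any(labels$end > dur + 0.5 / sample_rate)) {
    stop("label extends beyond the end of the audio")
  }
  lab_col <- if ("label" %in% names(labels)) labels$label
             else rep("", nrow(labels))
  out <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    i0 <- round(labels$start[i] * sample_rate) + 1L
    i1 <- round(labels$end[i] * sample_rate)
    x <- waveform[i0:min(i1, length(waveform))]
    peak <- max(abs(x))
    if (peak == 0) {
      if (!lenient) stop("labelled interval ", i, " contains no signal")
      seg_masked <- TRUE
    } else {
      x <- x / peak
      seg_masked <- FALSE
    }
    out[[i]] <- structure(list(start = labels$start[i], end = labels$end[i],
                               label = lab_col[i], samples = x,
                               masked = seg_masked),
                          class = "note_segment")
  }
  out
}

#' Assemble a song from note segments
#'
#' Splits an ordered note list into the introductory prefix and the trill
#' suffix. Acoustic measurements are made only in the trill; introductory
#' notes are carried for completeness.
#'
#' @param notes List of \code{note_segment}s, in time order.
#' @param n_intro Number of leading introductory notes; the remaining
#'   notes form the trill, which must be non-empty.
#' @param song_type,individual,sex,pair,date,context Song metadata.
#' @return A \code{song} object.
#' @export
song <- function(notes, n_intro = 0, song_type = NA_character_,
                 individual = NA_character_, sex = NA_character_,
                 pair = NA_character_, date = NA, context = NA_character_) {
  stopifnot(is.list(notes), n_intro >= 0, n_intro < length(notes))
  structure(list(
    notes = notes,
    n_intro = as.integer(n_intro),
    song_type = song_type, individual = individual, sex = sex,
    pair = pair, date = date, context = context
  ), class = "song")
}

#' Trill notes of a song
#' @param s A \code{song}.
#' @param usable_only Drop notes flagged \code{masked}.
#' @return List of \code{note_segment}s.
#' @export
trill_notes <- function(s, usable_only = TRUE) {
  stopifnot(inherits(s, "song"))
  tn <- s$notes[(s$n_intro + 1L):length(s$notes)]
  if (usable_only) {
    tn <- tn[!vapply(tn, function(n) isTRUE(n$masked), FALSE)]
  }
  tn
}

#' Flag masked notes within a song
#'
#' Notes masked by extraneous sound are excluded from feature
#' computation while the rest of the song is retained, which avoids
#' biasing the sample towards shorter songs. The song itself is only
#' dropped later, when its trill has no usable note left (or fewer than
#' three for trill rate and vocal deviation).
#'
#' @param s A \code{song}.
#' @param masked_flags Logical vector, one flag per note of the song.
#' @return The song with \code{masked} set on the flagged notes.
#' @export
apply_mask_filter <- function(s, masked_flags) {
  stopifnot(inherits(s, "song"), length(masked_flags) == length(s$notes))
  for (i in seq_along(s$notes)) {
    if (masked_flags[i]) s$notes[[i]]$masked <- TRUE
  }
  s
}

#' Longest run of consecutive unmasked trill notes
#'
#' Trill rate assumes contiguous renditions: a masked interior note
#' breaks the onset spacing, so the rate is computed on the longest
#' unmasked run.
#'
#' @param s A \code{song}.
#' @return List of \code{note_segment}s (possibly empty).
#' @export
longest_unmasked_run <- function(s) {
  tn <- trill_notes(s, usable_only = FALSE)
  ok <- !vapply(tn, function(n) isTRUE(n$masked), FALSE)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  tn[(ends[best] - r$lengths[best] + 1L):ends[best]]
}
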