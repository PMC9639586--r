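#' Specification of one synthetic song
#'
#' A song is rendered as a few high-pitched introductory notes followed by
#' a trill in which one note shape is repeated at a fixed rate. Trill note
#' onsets are spaced \code{1/trill_rate_true} apart before jitter, and the
#' note duration must leave a silent gap longer than 10 ms between
#' consecutive notes.
#'
#' @param n_intro_notes Number of introductory notes (>= 0).
#' @param n_trill_notes Number of trill notes (>= 1).
#' @param trill_rate_true Trill rate in notes per second.
#' @param note_duration Trill note duration in seconds; must satisfy
#'   \code{note_duration < 1/trill_rate_true - 0.010} so inter-note gaps
#'   exceed 10 ms.
#' @param peak_freq_true Centre frequency of trill notes, Hz.
#' @param bandwidth_true Frequency sweep extent per trill note, Hz.
#' @param consistency_jitter Non-negative scale of the multiplicative
#'   Gaussian perturbation applied to note frequency endpoints and
#'   duration; 0 renders sample-identical trill notes.
#' @param song_type_id Song type label.
#' @param noise_floor_db Additive white noise level in dB relative to the
#'   note peak; \code{-Inf} (default) renders noise-free audio.
#' @return An object of class \code{song_spec}.
#' @export
song_spec <- function(n_intro_notes = 2, n_trill_notes = 8,
                      trill_rate_true = 8.5, note_duration = 0.06,
                      peak_freq_true = 5000, bandwidth_true = 3000,
                      consistency_jitter = 0, song_type_id = "A",
                      noise_floor_db = -Inf) {
  stopifnot(n_intro_notes >= 0, n_trill_notes >= 1,
            trill_rate_true > 0, note_duration > 0,
            peak_freq_true > 0, bandwidth_true >= 0,
            consistency_jitter >= 0)
  gap <- 1 / trill_rate_true - note_duration
  if (gap <= 0.010) {
    stop("note_duration leaves an inter-note gap of ",
         sprintf("%.1f", gap * 1000),
         " ms; trill notes must be separated by gaps > 10 ms")
  }
  structure(list(
    n_intro_notes = as.integer(n_intro_notes),
    n_trill_notes = as.integer(n_trill_notes),
    trill_rate_true = trill_rate_true,
    note_duration = note_duration,
    peak_freq_true = peak_freq_true,
    bandwidth_true = bandwidth_true,
    consistency_jitter = consistency_jitter,
    song_type_id = as.character(song_type_id),
    noise_floor_db = noise_floor_db
  ), class = "song_spec")
}

#' Synthesize one tonal note
#'
#' Renders a linear frequency sweep under a cosine-tapered (Tukey)
#' amplitude envelope: the simplest signal giving a single continuous
#' spectrogram trace with controllable peak frequency and bandwidth. The
#' 10% edge taper avoids onset clicks while keeping nearly the whole
#' sweep extent above the -20 dB bandwidth threshold (a full-length
#' cosine envelope would suppress the sweep ends and shrink the measured
#' bandwidth well below the synthesized one).
#'
#' @param f_start,f_end Start and end frequency of the sweep, Hz; both
#'   must lie strictly inside (0, sample_rate/2).
#' @param duration Note duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param amplitude Peak sample amplitude on a 0-1 linear scale.
#' @return Numeric waveform whose maximum absolute sample equals
#'   \code{amplitude} (all zeros when \code{amplitude = 0}).
#' @examples
#' tone <- synth_note(4000, 4000, 0.1, 48000)
#' @export
synth_note <- function(f_start, f_end, duration, sample_rate = 48000,
                       amplitude = 1) {
  if (!(f_start > 0 && f_end > 0 &&
        f_start < sample_rate / 2 && f_end < sample_rate / 2)) {
    stop("note frequencies must lie strictly between 0 and sample_rate/2")
  }
  stopifnot(duration > 0, amplitude >= 0, amplitude <= 1)
  n <- max(2L, round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  # linear chirp: instantaneous frequency f_start + (f_end - f_start) t / T
  phase <- 2 * pi * (f_start * t + (f_end - f_start) * t^2 / (2 * duration))
  # Tukey envelope, 10% taper: flat top, raised-cosine edges
  u <- (seq_len(n) - 1) / (n - 1)
  a <- 0.1
  w <- rep(1, n)
  lo <- u < a / 2
  hi <- u > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (u[hi] - 1) / a + 1)))
  x <- sin(phase) * w
  if (amplitude == 0) return(numeric(n))
  x * (amplitude / max(abs(x)))
}

#' Synthesize one song and its label track
#'
#' Renders the introductory notes and trill described by a
#' [song_spec()] into a waveform plus a ground-truth label track. With
#' \code{consistency_jitter = 0} every trill note is sample-identical and
#' trill onsets are spaced exactly \code{1/trill_rate_true} apart.
#' Introductory notes are short down-sweeps pitched above the trill.
#'
#' @param spec A [song_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param pad Leading/trailing silence, seconds.
#' @return A list with \code{waveform}, \code{sample_rate} and
#'   \code{labels} (data frame \code{start}, \code{end}, \code{label};
#'   intro notes labelled \code{"i"}, trill notes \code{"t"}).
#' @export
synth_song <- function(spec, sample_rate = 48000, pad = 0.05) {
  stopifnot(inherits(spec, "song_spec"))
  period <- 1 / spec$trill_rate_true
  jit <- function(k) {
    if (spec$consistency_jitter == 0) rep(1, k)
    else pmax(0.2, 1 + stats::rnorm(k, 0, spec$consistency_jitter))
  }

  notes <- list()
  starts <- numeric(0)
  labels <- character(0)
  t_cursor <- pad

  # introduction: high-pitched short down-sweeps above the trill band
  if (spec$n_intro_notes > 0) {
    f_hi <- min(spec$peak_freq_true + spec$bandwidth_true / 2 + 1500,
                0.45 * sample_rate)
    intro_dur <- min(spec$note_duration, 0.05)
    for (i in seq_len(spec$n_intro_notes)) {
      notes[[length(notes) + 1L]] <-
        synth_note(f_hi, f_hi - 500, intro_dur, sample_rate)
      starts <- c(starts, t_cursor)
      labels <- c(labels, "i")
      t_cursor <- t_cursor + intro_dur + 0.04
    }
    t_cursor <- t_cursor + 0.05  # pause before the trill
  }

  # trill: repeated sweep through [peak - bw/2, peak + bw/2]
  f_top <- spec$peak_freq_true + spec$bandwidth_true / 2
  f_bot <- spec$peak_freq_true - spec$bandwidth_true / 2
  if (f_bot <= 0 || f_top >= sample_rate / 2) {
    stop("trill frequency band outside (0, sample_rate/2)")
  }
  trill_t0 <- t_cursor
  fj_a <- jit(spec$n_trill_notes)
  fj_b <- jit(spec$n_trill_notes)
  dj <- jit(spec$n_trill_notes)
  for (i in seq_len(spec$n_trill_notes)) {
    dur <- spec$note_duration * dj[i]
    dur <- min(dur, period - 0.011)  # keep >10 ms gaps under jitter
    notes[[length(notes) + 1L]] <-
      synth_note(min(f_top * fj_a[i], 0.49 * sample_rate),
                 max(f_bot * fj_b[i], 10), dur, sample_rate)
    starts <- c(starts, trill_t0 + (i - 1) * period)
    labels <- c(labels, "t")
  }

  ends <- starts + vapply(notes, length, 1L) / sample_rate
  n_total <- ceiling((max(ends) + pad) * sample_rate)
  wave <- numeric(n_total)
  for (i in seq_along(notes)) {
    i0 <- round(starts[i] * sample_rate)
    idx <- i0 + seq_along(notes[[i]])
    wave[idx] <- wave[idx] + notes[[i]]
  }
  if (is.finite(spec$noise_floor_db)) {
    wave <- wave + stats::rnorm(n_total, 0, 10^(spec$noise_floor_db / 20))
  }
  lab <- data.frame(start = starts, end = ends, label = labels,
                    stringsAsFactors = FALSE)
  list(waveform = wave, sample_rate = sample_rate, labels = lab)
}
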