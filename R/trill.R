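#' Trill length
#'
#' Duration of the trill from the start of the first usable note to the
#' end of the last.
#'
#' @param notes List of \code{note_segment}s (the usable trill notes).
#' @return Seconds, or \code{NA} when the trill has no usable note.
#' @export
trill_length <- function(notes) {
  if (length(notes) == 0) return(NA_real_)
  notes[[length(notes)]]$end - notes[[1]]$start
}

#' Trill rate
#'
#' Number of notes per second excluding the last rendition, divided by
#' the time from the start of the first note to the start of the last:
#' \code{(N - 1) / onset span}. Every counted note carries its inter-note
#' gap except the last, so this estimator is unbiased with respect to the
#' number of renditions. Defined only for trills of at least three
#' consecutive notes; masked interior notes break the onset spacing, so
#' callers should pass the longest unmasked run
#' (see [longest_unmasked_run()]).
#'
#' @param notes List of consecutive \code{note_segment}s.
#' @return Notes per second, or \code{NA} when fewer than 3 notes.
#' @export
trill_rate <- function(notes) {
  n <- length(notes)
  if (n < 3) return(NA_real_)
  span <- notes[[n]]$start - notes[[1]]$start
  (n - 1) / span
}

#' Spectrogram matrix of a note for cross-correlation
#'
#' 512-sample Hann windows with 90% overlap, power in dB floored at
#' -80 dB relative to the matrix maximum.
#'
#' @param x Numeric waveform.
#' @param sample_rate Sampling rate, Hz.
#' @param n_fft Window size (samples).
#' @param overlap Overlap between successive windows (samples).
#' @param floor_db Dynamic-range floor in dB.
#' @return Matrix, frequency bins x time frames, plus attribute
#'   \code{hop_s} (frame step in seconds).
#' @keywords internal
note_spectrogram <- function(x, sample_rate = 48000, n_fft = 512,
                             overlap = round(0.9 * 512), floor_db = -80) {
  if (length(x) < n_fft) x <- c(x, numeric(n_fft - length(x)))
  sg <- signal::specgram(x, n = n_fft, Fs = sample_rate,
                         window = signal::hanning(n_fft), overlap = overlap)
  p <- Mod(sg$S)^2
  p_db <- 10 * log10(pmax(p / max(p), 10^(floor_db / 10)))
  hop <- (n_fft - overlap) / sample_rate
  attr(p_db, "hop_s") <- hop
  p_db
}

#' Spectrogram cross-correlation of two notes
#'
#' Slides the shorter spectrogram over the longer one and returns the
#' maximum Pearson correlation of the overlapping time-frequency cells,
#' searching temporal offsets up to \code{max_offset_s} around every
#' alignment at the spectrogram frame resolution (~1 ms at 48 kHz with
#' 512-sample windows and 90% overlap).
#'
#' @param note_a,note_b \code{note_segment}s or bare waveforms.
#' @param sample_rate Sampling rate, Hz.
#' @param max_offset_s Maximum temporal offset searched, seconds.
#' @return Maximum correlation in \code{[-1, 1]}, or \code{NA} if either
#'   note is silent.
#' @export
spcc_pair <- function(note_a, note_b, sample_rate = 48000,
                      max_offset_s = 0.020) {
  xa <- if (inherits(note_a, "note_segment")) note_a$samples else note_a
  xb <- if (inherits(note_b, "note_segment")) note_b$samples else note_b
  if (all(xa == 0) || all(xb == 0)) return(NA_real_)
  A <- note_spectrogram(xa, sample_rate)
  B <- note_spectrogram(xb, sample_rate)
  if (ncol(A) > ncol(B)) { tmp <- A; A <- B; B <- tmp }
  hop <- attr(A, "hop_s")
  k_max <- floor(max_offset_s / hop)
  na <- ncol(A); nb <- ncol(B)
  best <- -1
  for (d in seq(-k_max, (nb - na) + k_max)) {
    ia <- max(1L, 1L - d):min(na, nb - d)
    if (length(ia) < 3L) next
    va <- as.vector(A[, ia])
    vb <- as.vector(B[, ia + d])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    r <- stats::cor(va, vb)
    if (r > best) best <- r
  }
  best
}

#' Vocal consistency of a trill
#'
#' Acoustic similarity between each note and its consecutive rendition
#' within the trill: the mean of the maximum spectrogram
#' cross-correlation ([spcc_pair()]) over all consecutive usable pairs.
#' Higher values mean more stereotyped repetition.
#'
#' @param notes List of usable trill \code{note_segment}s, in order.
#' @param sample_rate Sampling rate, Hz.
#' @return Mean SPCC score, or \code{NA} when fewer than 2 usable notes.
#' @export
vocal_consistency <- function(notes, sample_rate = 48000) {
  n <- length(notes)
  if (n < 2) return(NA_real_)
  scores <- vapply(seq_len(n - 1), function(i) {
    spcc_pair(notes[[i]], notes[[i + 1]], sample_rate)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}
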