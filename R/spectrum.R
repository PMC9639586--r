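#' Mean power spectrum of a note
#'
#' Averages the power spectrum over successive 1024-sample Hann windows
#' (Welch averaging, 50% overlap, with the final window snapped to the
#' note end so the whole note contributes) and expresses it in dB
#' relative to the spectrum maximum (so the peak bin sits at 0 dB).
#' Notes shorter than one window are zero-padded to 1024 samples, with a
#' warning.
#'
#' @param note A \code{note_segment} or a bare numeric waveform.
#' @param sample_rate Sampling rate, Hz.
#' @param n_fft Window size in samples.
#' @return A \code{note_spectrum}: list with \code{freq} (Hz, grid
#'   spacing \code{sample_rate/n_fft}) and \code{power_db} (dB re max).
#' @export
mean_power_spectrum <- function(note, sample_rate = 48000, n_fft = 1024) {
  x <- if (inherits(note, "note_segment")) note$samples else note
  stopifnot(is.numeric(x))
  if (all(x == 0)) stop("silent note: dB reference undefined")
  if (length(x) < n_fft) {
    warning("note shorter than one FFT window (", length(x),
            " < ", n_fft, " samples); zero-padding")
    x <- c(x, numeric(n_fft - length(x)))
  }
  starts <- unique(c(seq(1L, length(x) - n_fft + 1L, by = n_fft %/% 2L),
                     length(x) - n_fft + 1L))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / (n_fft - 1))
  acc <- numeric(n_fft %/% 2)
  for (s in starts) {
    seg <- x[s:(s + n_fft - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))[seq_len(n_fft %/% 2)]^2
  }
  acc <- acc / length(starts)
  if (max(acc) == 0) stop("silent note: dB reference undefined")
  structure(list(
    freq = (seq_len(n_fft %/% 2) - 1) * sample_rate / n_fft,
    power_db = 10 * log10(acc / max(acc))
  ), class = "note_spectrum")
}

#' Peak frequency of a note spectrum
#'
#' The frequency with the maximum amplitude in the mean power spectrum.
#' Ties are broken towards the lowest frequency, for determinism.
#'
#' @param spec A \code{note_spectrum}.
#' @return Frequency in Hz.
#' @export
peak_frequency <- function(spec) {
  stopifnot(inherits(spec, "note_spectrum"))
  spec$freq[which.max(spec$power_db)]
}

#' Frequency extent of a note at an amplitude threshold
#'
#' Minimum and maximum frequency whose power reaches
#' \code{threshold_db} relative to the spectral peak, and their
#' difference (the bandwidth).
#'
#' @param spec A \code{note_spectrum}.
#' @param threshold_db Amplitude threshold in dB re the peak
#'   (default -20).
#' @return Named numeric vector \code{min_freq}, \code{max_freq},
#'   \code{bandwidth}, all in Hz.
#' @export
freq_extent <- function(spec, threshold_db = -20) {
  stopifnot(inherits(spec, "note_spectrum"))
  above <- which(spec$power_db >= threshold_db)
  if (length(above) == 0) stop("no bin reaches the threshold")
  c(min_freq = spec$freq[min(above)],
    max_freq = spec$freq[max(above)],
    bandwidth = spec$freq[max(above)] - spec$freq[min(above)])
}
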