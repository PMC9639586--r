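#' Read a mono RIFF PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed mono PCM files this
#' package writes and consumes (16- or 24-bit integer samples). Samples
#' are returned as doubles in \code{[-1, 1]}.
#'
#' @param path Path to a \code{.wav} file.
#' @return A list with elements \code{samples} (numeric vector, amplitude
#'   in \code{[-1, 1]}) and \code{sample_rate} (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = bytes_le(body[1:2]),
        n_channels   = bytes_le(body[3:4]),
        sample_rate  = bytes_le(body[5:8]),
        bits         = bytes_le(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip unknown chunk
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1L) stop("only PCM WAV supported")
  if (fmt$n_channels != 1L) stop("only mono WAV supported")

  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) / 2L,
                 size = 2, signed = TRUE, endian = "little")
    samples <- x / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    x <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    x <- ifelse(x >= 8388608, x - 16777216, x)
    samples <- x / 8388608
  } else {
    stop("unsupported bit depth: ", fmt$bits)
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}

bytes_le <- function(b) sum(as.integer(b) * 256L^(seq_along(b) - 1L))

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector of amplitudes; values are clipped to
#'   \code{[-1, 1]} before quantization.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  x <- pmax(-1, pmin(1, samples))
  q <- pmin(as.integer(round(x * 32768)), 32767L)  # symmetric with read scale
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
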