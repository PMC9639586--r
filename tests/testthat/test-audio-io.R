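test_that("WAV round-trip preserves mono 16-bit samples and rate", {
  x <- sin(2 * pi * 440 * (0:4799) / 48000) * 0.8
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 48000, f)
  w <- read_wav(f)
  expect_equal(w$sample_rate, 48000)
  expect_equal(length(w$samples), length(x))
  expect_lt(max(abs(w$samples - x)), 1 / 32767)
})

test_that("24-bit PCM WAV files are read correctly", {
  # hand-build a tiny 24-bit mono file
  vals <- c(0L, 8388607L, -8388608L, 4194304L)
  raw3 <- unlist(lapply(vals, function(v) {
    if (v < 0) v <- v + 16777216L
    as.raw(c(v %% 256L, (v %/% 256L) %% 256L, v %/% 65536L))
  }))
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(raw3)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  for (v in c(1L, 1L)) writeBin(v, con, size = 2, endian = "little")
  writeBin(48000L, con, size = 4, endian = "little")
  writeBin(48000L * 3L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(raw3), con, size = 4, endian = "little")
  writeBin(raw3, con)
  close(con)
  w <- read_wav(f)
  expect_equal(w$samples, vals / 8388608, tolerance = 1e-12)
})

test_that("label tracks parse, sort, and round-trip to a microsecond", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0.000000\t0.080000\ta", f)
  d <- read_label_track(f)
  expect_equal(d$start, 0)
  expect_equal(d$end, 0.08)
  expect_equal(d$label, "a")

  writeLines(character(0), f)
  expect_equal(nrow(read_label_track(f)), 0)

  writeLines(c("0.50\t0.60\tb", "0.10\t0.20\ta"), f)
  d <- read_label_track(f)
  expect_equal(d$label, c("a", "b"))
  expect_true(!is.unsorted(d$start))

  writeLines("0.1\tx\ta", f)
  expect_error(read_label_track(f), "non-numeric")
  writeLines(c("0.1\t0.5\ta", "0.3\t0.7\tb"), f)
  expect_error(read_label_track(f), "overlap")

  lab <- data.frame(start = c(0.1234567, 2), end = c(0.2234567, 2.5),
                    label = c("i", "t"))
  write_label_track(lab, f)
  back <- read_label_track(f)
  expect_lt(max(abs(back$start - lab$start)), 1e-6)
  expect_lt(max(abs(back$end - lab$end)), 1e-6)
})

test_that("note cutting is content-preserving and peak-normalizes", {
  sr <- 48000
  x <- numeric(sr)
  seg <- 0.3 * sin(2 * pi * 3000 * (0:(0.1 * sr - 1)) / sr)
  x[2401:(2400 + length(seg))] <- seg
  labels <- data.frame(start = 0.05, end = 0.15, label = "a")
  notes <- cut_and_normalize_notes(x, labels, sr)
  expect_length(notes, 1)
  expect_equal(max(abs(notes[[1]]$samples)), 1)
  # samples equal the source slice up to the normalization scalar
  src <- x[2401:(2400 + length(seg))]
  expect_equal(notes[[1]]$samples * max(abs(src)), src, tolerance = 1e-12)

  two <- data.frame(start = c(0.05, 0.12), end = c(0.1, 0.15),
                    label = c("a", "b"))
  notes2 <- cut_and_normalize_notes(x, two, sr)
  expect_equal(vapply(notes2, function(n) length(n$samples), 1) / sr,
               two$end - two$start, tolerance = 1.5 / sr)

  silent <- data.frame(start = 0.5, end = 0.6, label = "s")
  expect_error(cut_and_normalize_notes(x, silent, sr), "no signal")
  lenient <- cut_and_normalize_notes(x, silent, sr, lenient = TRUE)
  expect_true(lenient[[1]]$masked)

  beyond <- data.frame(start = 0.9, end = 1.2, label = "z")
  expect_error(cut_and_normalize_notes(x, beyond, sr), "beyond")
})

test_that("mask filter drops notes from measurement but keeps the song", {
  fx <- render_clean_song(n_trill = 10)
  s <- fx$song
  flags <- rep(FALSE, length(s$notes))
  flags[5] <- TRUE  # one trill note masked
  s2 <- apply_mask_filter(s, flags)
  expect_length(trill_notes(s2), 9)
  expect_length(trill_notes(s2, usable_only = FALSE), 10)
  # masked interior note breaks the run used for trill rate
  run <- longest_unmasked_run(s2)
  expect_length(run, 7)

  all_masked <- apply_mask_filter(s, c(FALSE, FALSE, rep(TRUE, 10)))
  expect_equal(measure_song(all_masked)$n_notes_used, 0)
  expect_message(
    tab <- song_feature_table(list(all_masked), deviation = FALSE),
    "no usable trill note"
  )
  expect_equal(nrow(tab), 0)
})

test_that("masking ~7% of notes shifts feature means by under 2%", {
  set.seed(42)
  clean <- lapply(1:20, function(i) render_clean_song(n_trill = 15)$song)
  masked <- lapply(clean, function(s) {
    flags <- c(FALSE, FALSE, stats::runif(15) < 0.07)
    if (all(flags[-(1:2)])) flags[3] <- FALSE
    apply_mask_filter(s, flags)
  })
  m0 <- do.call(rbind, lapply(clean, measure_song))
  m1 <- do.call(rbind, lapply(masked, measure_song))
  for (col in c("peak_freq", "bandwidth", "vocal_consistency",
                "trill_rate", "trill_length")) {
    expect_lt(abs(mean(m1[[col]]) - mean(m0[[col]])) / mean(m0[[col]]),
              0.02)
  }
})
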