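test_that("mean power spectrum localizes tones and is flat for noise", {
  tone <- synth_note(4000, 4000, 0.2, 48000)
  sp <- mean_power_spectrum(tone, 48000)
  expect_s3_class(sp, "note_spectrum")
  expect_equal(max(sp$power_db), 0)
  expect_equal(diff(sp$freq)[1], 48000 / 1024)
  expect_lt(abs(sp$freq[which.max(sp$power_db)] - 4000), 48000 / 1024)

  set.seed(1)
  noise <- stats::rnorm(1024 * 100)
  spn <- mean_power_spectrum(noise, 48000)
  inner <- spn$power_db[5:(length(spn$power_db) - 4)]
  expect_lt(max(inner) - min(inner), 6)  # flat within +/- 3 dB

  expect_error(mean_power_spectrum(numeric(2048), 48000), "silent")
  expect_warning(mean_power_spectrum(synth_note(4000, 4000, 0.005, 48000),
                                     48000), "zero-padding")
})

test_that("peak frequency takes the strongest bin, lowest tie first", {
  sr <- 48000
  t <- (0:(0.2 * sr - 1)) / sr
  two <- sin(2 * pi * 5000 * t) + 0.5 * sin(2 * pi * 3000 * t)  # 6 dB apart
  sp <- mean_power_spectrum(two, sr)
  expect_lt(abs(peak_frequency(sp) - 5000), sr / 1024)

  sweep <- synth_note(3000, 6000, 0.1, sr)
  sps <- mean_power_spectrum(sweep, sr)
  # brute-force argmax over the same grid
  expect_equal(peak_frequency(sps), sps$freq[which.max(sps$power_db)])

  tie <- sp
  tie$power_db[] <- -30
  tie$power_db[c(10, 40)] <- 0
  expect_equal(peak_frequency(tie), tie$freq[10])
})

test_that("-20 dB frequency extent matches a threshold-crossing oracle", {
  sr <- 48000
  sweep <- synth_note(3000, 6000, 0.1, sr)
  sp <- mean_power_spectrum(sweep, sr)
  ext <- freq_extent(sp)
  expect_lt(abs(ext[["bandwidth"]] - 3000) / 3000, 0.10)
  expect_true(ext[["min_freq"]] <= peak_frequency(sp))
  expect_true(ext[["max_freq"]] >= peak_frequency(sp))
  # independent recount of threshold crossings
  above <- sp$freq[sp$power_db >= -20]
  expect_equal(unname(ext[["min_freq"]]), min(above))
  expect_equal(unname(ext[["max_freq"]]), max(above))

  full <- freq_extent(sp, threshold_db = -Inf)
  expect_equal(unname(full[["min_freq"]]), sp$freq[1])
  expect_equal(unname(full[["max_freq"]]), sp$freq[length(sp$freq)])

  tone <- synth_note(4000, 4000, 0.1, sr)
  expect_lt(freq_extent(mean_power_spectrum(tone, sr))[["bandwidth"]],
            5 * sr / 1024)
})

test_that("trill length and trill rate follow their closed forms", {
  one <- timing_notes(0.10, dur = 0.08)
  expect_equal(trill_length(one), 0.08)
  nine <- timing_notes(seq(0, by = 0.125, length.out = 9), dur = 0.08)
  expect_equal(trill_length(nine), 1.08)
  expect_equal(trill_rate(nine), 8)
  three <- timing_notes(c(0, 0.2, 0.4))
  expect_equal(trill_rate(three), 5)
  expect_equal(trill_rate(timing_notes(c(0, 0.2))), NA_real_)
  expect_equal(trill_length(list()), NA_real_)

  # jittered onsets: direct recount oracle, plus translation invariance
  set.seed(3)
  for (r in 1:20) {
    n <- sample(3:12, 1)
    onsets <- sort(stats::runif(n, 0, 2))
    notes <- timing_notes(onsets, dur = 0.01)
    expect_equal(trill_rate(notes), (n - 1) / (max(onsets) - min(onsets)))
    shifted <- timing_notes(onsets + 5, dur = 0.01)
    expect_equal(trill_rate(shifted), trill_rate(notes), tolerance = 1e-9)
  }
})

test_that("SPCC scores identity, tolerates shifts, rejects noise", {
  sr <- 48000
  note <- synth_note(4000, 6000, 0.06, sr)
  expect_equal(spcc_pair(note, note, sr), 1, tolerance = 1e-6)
  # symmetric
  other <- synth_note(5000, 3500, 0.05, sr)
  expect_equal(spcc_pair(note, other, sr), spcc_pair(other, note, sr),
               tolerance = 1e-9)
  # 10 ms shift inside a longer clip stays within the search window
  clip <- c(numeric(round(0.010 * sr)), note, numeric(round(0.020 * sr)))
  expect_gte(spcc_pair(note, clip, sr), 0.99)
  # amplitude scale invariance
  expect_equal(spcc_pair(note, 0.2 * note, sr), 1, tolerance = 1e-6)

  set.seed(9)
  worst <- max(vapply(1:100, function(i) {
    spcc_pair(note, stats::rnorm(length(note), 0, 0.3), sr)
  }, numeric(1)))
  expect_lt(worst, 0.5)

  expect_true(is.na(spcc_pair(note, numeric(2000), sr)))
})

test_that("vocal consistency averages consecutive pairs and is scale-free", {
  sr <- 48000
  a <- synth_note(4000, 6000, 0.06, sr)
  b <- synth_note(6000, 4000, 0.06, sr)
  seg <- function(x, t0) structure(
    list(start = t0, end = t0 + 0.06, label = "t", samples = x,
         masked = FALSE), class = "note_segment")
  same <- list(seg(a, 0), seg(a, 0.125), seg(a, 0.25))
  expect_equal(vocal_consistency(same, sr), 1, tolerance = 1e-6)
  alt <- list(seg(a, 0), seg(b, 0.125), seg(a, 0.25))
  expect_lt(vocal_consistency(alt, sr), vocal_consistency(same, sr))
  # uniform amplitude scaling leaves the score unchanged
  scaled <- lapply(same, function(n) { n$samples <- n$samples * 0.3; n })
  expect_equal(vocal_consistency(scaled, sr), vocal_consistency(same, sr),
               tolerance = 1e-9)
  expect_true(is.na(vocal_consistency(same[1], sr)))
})

test_that("vocal consistency recovers the calibrated female mean", {
  # generator default: female intercept 0.867 at the average season
  cfg <- population_config(n_pairs = 25, seed = 31)
  pop <- synth_population(cfg)
  f <- pop$songs[pop$songs$sex == "F", ]
  centre <- stats::lm(vocal_consistency ~ weeks_to_egg, data = f)
  pred <- unname(predict(centre, data.frame(weeks_to_egg = 0)))
  expect_lt(abs(pred - 0.867), 0.05)
})

test_that("peak and maximum frequency are strongly correlated on song data", {
  set.seed(12)
  feats <- do.call(rbind, lapply(1:15, function(i) {
    peak <- stats::runif(1, 3500, 6500)
    bw <- stats::runif(1, 1500, 3500)
    fx <- render_clean_song(n_trill = 3, peak = peak, bw = bw)
    measure_song(fx$song)
  }))
  expect_gt(stats::cor(feats$peak_freq, feats$max_freq), 0.85)
  expect_true(all(feats$min_freq <= feats$peak_freq))
  expect_true(all(feats$peak_freq <= feats$max_freq))
  expect_equal(feats$bandwidth, feats$max_freq - feats$min_freq,
               tolerance = 1e-9)
})
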