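# Shared fixtures, all generated in code.

# a clean rendered song: 2 intro + n trill notes, no jitter, no noise
render_clean_song <- function(n_trill = 5, rate = 8, dur = 0.06,
                              peak = 5000, bw = 3000, jitter = 0,
                              sr = 48000) {
  spec <- song_spec(n_intro_notes = 2, n_trill_notes = n_trill,
                    trill_rate_true = rate, note_duration = dur,
                    peak_freq_true = peak, bandwidth_true = bw,
                    consistency_jitter = jitter)
  sg <- synth_song(spec, sr)
  notes <- cut_and_normalize_notes(sg$waveform, sg$labels, sr)
  list(song = song(notes, n_intro = 2), render = sg, sr = sr)
}

# note segments at given onsets, without any audio (timing-only tests)
timing_notes <- function(onsets, dur = 0.06) {
  lapply(onsets, function(t0) {
    structure(list(start = t0, end = t0 + dur, label = "t",
                   samples = numeric(0), masked = FALSE),
              class = "note_segment")
  })
}

# song-level analysis frame from a seeded population, ready for the LMMs
analysis_frame <- function(pop) {
  songs <- pop$songs
  songs$weeks_s <- scale_center(songs$weeks_to_egg)
  songs$sex <- factor(songs$sex, levels = c("F", "M"))
  songs$age_c <- as.numeric(songs$age == "older")
  songs$age_c <- songs$age_c - mean(songs$age_c)
  songs
}
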