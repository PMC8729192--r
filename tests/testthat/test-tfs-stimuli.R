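# Complex-tone synthesis, band-limiting, pink noise and trial assembly.

test_that("synthesized complexes place components at k*f0 + delta_f", {
  for (df in c(0, 50)) {
    sp <- complex_tone_spec(f0 = 100, delta_f = df, duration = 1,
                            phase_seed = 7)
    tone <- synthesize_complex(sp)
    pg <- oracle_periodogram(tone$samples, sp$sample_rate)
    # the 18 strongest periodogram bins must sit on the component grid
    top <- order(pg$spec, decreasing = TRUE)[1:18]
    peaks <- sort(pg$freq[top])
    expect_equal(peaks, 1:18 * 100 + df, tolerance = 0.03)
  }
})

test_that("pre-filter component amplitudes are equal", {
  sp <- complex_tone_spec(duration = 1, ramp = 0, phase_seed = 2)
  tone <- synthesize_complex(sp)
  amp <- sapply(1:18 * 100, function(f)
    oracle_component_amp(tone$samples, sp$sample_rate, f))
  spread_db <- 20 * (log10(max(amp)) - log10(min(amp)))
  expect_lt(spread_db, 0.01)
})

test_that("synthesis is a pure function of spec and phase seed", {
  sp <- complex_tone_spec(delta_f = 10, phase_seed = 42)
  expect_identical(synthesize_complex(sp)$samples,
                   synthesize_complex(sp)$samples)
  sp2 <- complex_tone_spec(delta_f = 10, phase_seed = 43)
  expect_false(identical(synthesize_complex(sp)$samples,
                         synthesize_complex(sp2)$samples))
})

test_that("components above Nyquist are rejected, not dropped", {
  expect_error(synthesize_complex(
    complex_tone_spec(f0 = 100, n_components = 300, sample_rate = 44100)),
    "Nyquist")
  expect_error(complex_tone_spec(f0 = 2000, sample_rate = 8000),
               "sample_rate")
})

test_that("band-limited complex concentrates power in 850-1350 Hz", {
  for (df in c(0, 50)) {
    sp <- complex_tone_spec(delta_f = df, duration = 0.5, phase_seed = 5)
    tone <- bandlimit(synthesize_complex(sp), sp)
    expect_gt(oracle_band_fraction(tone$samples, sp$sample_rate,
                                   850, 1350), 0.99)
  }
})

test_that("filter attenuates rank 7 by at least 20 dB re passband", {
  # pre-filter components are equal-amplitude, so the post-filter
  # rank-7 : rank-10 amplitude ratio is the relative attenuation and
  # is immune to the output peak normalization
  sp <- complex_tone_spec(duration = 1, phase_seed = 4)
  tone <- bandlimit(synthesize_complex(sp), sp)
  pg <- oracle_periodogram(tone$samples, sp$sample_rate)
  amp_at <- function(f) sqrt(max(pg$spec[abs(pg$freq - f) < 3]))
  expect_gt(20 * log10(amp_at(1000) / amp_at(700)), 20)
  expect_gt(20 * log10(amp_at(1000) / amp_at(1500)), 20)
})

test_that("cascading the filter steepens skirts but keeps the passband", {
  fs <- 44100
  t <- seq_len(fs) / fs
  bf <- signal::butter(5, c(900, 1300) / (fs / 2), type = "pass")
  gain <- function(x, hz) 20 * log10(stats::sd(x[2000:(fs - 2000)]) /
                                       stats::sd(sin(2 * pi * hz * t)))
  for (hz in c(1000, 1100)) {
    s <- sin(2 * pi * hz * t)
    once <- signal::filtfilt(bf, s)
    twice <- signal::filtfilt(bf, once)
    expect_lt(abs(gain(twice, hz) - gain(once, hz)), 0.2)
  }
  s7 <- sin(2 * pi * 700 * t)
  once7 <- signal::filtfilt(bf, s7)
  twice7 <- signal::filtfilt(bf, once7)
  expect_lt(gain(twice7, 700), gain(once7, 700) - 10)
})

test_that("pink noise has 1/f PSD: slope, octave energy, determinism", {
  pn <- pink_noise(2, seed = 11)
  slope <- oracle_psd_slope(pn$samples, pn$sample_rate, 100, 5000)
  expect_equal(slope, -1, tolerance = 0.15)
  # equal energy per octave: 200-400 vs 400-800 within 1 dB
  pg <- oracle_periodogram(pn$samples, pn$sample_rate)
  band <- function(lo, hi) sum(pg$spec[pg$freq >= lo & pg$freq < hi])
  ratio_db <- 10 * log10(band(200, 400) / band(400, 800))
  expect_lt(abs(ratio_db), 1)
  expect_identical(pink_noise(0.5, seed = 3)$samples,
                   pink_noise(0.5, seed = 3)$samples)
})

test_that("trial assembly: durations, target randomization, degenerate df", {
  cfg <- trial_config()
  expect_equal(trial_duration(cfg), 2 * (4 * 0.2 + 3 * 0.1) + 0.5)
  tr <- build_trial(30, cfg, seed = 5)
  expect_equal(length(tr$samples),
               round(trial_duration(cfg) * cfg$sample_rate))
  expect_true(tr$target_interval %in% 1:2)
  # target side is uniform over seeds
  sides <- vapply(1:1000, function(s)
    with_seed(substream(s, "order"), sample(1:2, 1)), numeric(1))
  expect_equal(mean(sides == 1), 0.5, tolerance = 0.05)
  # delta_f = 0 degenerates I to H: every tone in both intervals is
  # harmonic, carrying the 900-1300 Hz band and a suppressed rank 7
  tr0 <- build_trial(0, cfg, seed = 9)
  for (iv in list(tr0$interval_1, tr0$interval_2)) {
    for (tone in iv) {
      expect_identical(tone$label, "H")
      amp <- function(f) oracle_component_amp(tone$samples,
                                              cfg$sample_rate, f)
      passband <- sapply(c(900, 1000, 1100, 1200, 1300), amp)
      expect_gt(20 * log10(min(passband) / amp(700)), 20)
      expect_gt(20 * log10(min(passband) / amp(1500)), 20)
    }
  }
})

test_that("stimuli round-trip through WAV at 16-bit precision", {
  sp <- complex_tone_spec(phase_seed = 8)
  tone <- bandlimit(synthesize_complex(sp), sp)
  path <- tempfile(fileext = ".wav")
  on.exit(unlink(path))
  write_wav(tone$samples, path, tone$sample_rate)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100)
  expect_equal(back$samples, tone$samples, tolerance = 1e-4)
})
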