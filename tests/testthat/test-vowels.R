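# Vowel synthesis, token/pair enumeration, mixing.

test_that("semitone arithmetic is exact and additive", {
  expect_equal(shift_f0(200, 0), 200)
  expect_equal(shift_f0(200, 12), 400)
  # closed form: 200 * 2^(4/12) = 200 * 2^(1/3)
  expect_equal(shift_f0(200, 4), 200 * 2^(1 / 3))
  expect_equal(round(shift_f0(200, 4), 3), 251.984)
  for (a in c(-3, 0, 1.5)) for (b in c(2, 4))
    expect_equal(shift_f0(shift_f0(220, a), b), shift_f0(220, a + b))
})

test_that("synthesized vowels have the specified duration and F0", {
  v <- synthesize_vowel(vowel_spec("a", f0 = 200))
  expect_length(v$samples, round(0.270 * 44100))
  expect_length(v$samples, 11907)
  for (id in c("a", "i", "o")) {
    for (f0 in c(200, shift_f0(200, 4))) {
      w <- synthesize_vowel(vowel_spec(id, f0 = f0))
      expect_equal(oracle_f0(w$samples, 44100), f0, tolerance = 2 / f0)
    }
  }
})

test_that("spectral envelope peaks track the configured low formants", {
  # envelope is sampled at the 200 Hz harmonic grid, so a formant is
  # confirmed when the nearest envelope peak lies within one harmonic
  # spacing of the configured centre
  for (id in c("a", "i", "u")) {
    spec <- vowel_spec(id, f0 = 200)
    w <- synthesize_vowel(spec)
    est <- oracle_formants(w$samples, 44100, f0 = 200, n_formants = 2)
    expect_lt(abs(est[1] - spec$formants["F1", "freq"]), 200)
    expect_lt(abs(est[2] - spec$formants["F2", "freq"]), 200)
  }
})

test_that("formants above Nyquist are rejected", {
  bad <- vowel_spec("a", f0 = 200, sample_rate = 6000)
  expect_error(synthesize_vowel(bad), "Nyquist")
})

test_that("token enumeration covers identities x F0 conditions", {
  expect_equal(nrow(enumerate_tokens(200, shifts = c(1, 2, 4))), 20)
  expect_equal(nrow(enumerate_tokens(200, shifts = numeric(0),
                                     identities = "a")), 1)
  expect_equal(nrow(enumerate_tokens(200, shifts = numeric(0))), 5)
  tk <- enumerate_tokens(200, shifts = c(1, 2, 4))
  expect_setequal(unique(tk$shift_semitones), c(0, 1, 2, 4))
  expect_equal(sort(unique(round(tk$f0, 3))),
               sort(round(shift_f0(200, c(0, 1, 2, 4)), 3)))
})

test_that("pair enumeration: C(5,2) per condition, no self-pairs, closure", {
  tk <- enumerate_tokens(200, shifts = c(1, 2, 4))
  pairs <- enumerate_pairs(tk)
  expect_equal(nrow(pairs), choose(5, 2) * 4)
  expect_equal(as.vector(table(pairs$semitone_diff)), rep(10, 4))
  expect_true(all(pairs$vowel_1 != pairs$vowel_2))
  # every member exists in the token set at its assigned F0
  key <- paste(tk$identity, round(tk$f0, 6))
  expect_true(all(paste(pairs$vowel_1, round(pairs$f0_1, 6)) %in% key))
  expect_true(all(paste(pairs$vowel_2, round(pairs$f0_2, 6)) %in% key))
  # F0 ratio of the members expresses the condition's semitone difference
  expect_equal(abs(12 * log2(pairs$f0_1 / pairs$f0_2)),
               pairs$semitone_diff)
  # degenerate: two identities, one condition
  p1 <- enumerate_pairs(enumerate_tokens(200, shifts = numeric(0),
                                         identities = c("a", "i")),
                        diffs = 0)
  expect_equal(nrow(p1), 1)
})

test_that("mixing equalizes member RMS and preserves both harmonic series", {
  w1 <- synthesize_vowel(vowel_spec("a", f0 = 200))
  w2 <- synthesize_vowel(vowel_spec("i", f0 = shift_f0(200, 4)))
  mix <- mix_pair(w1, w2)
  expect_lte(max(abs(mix$samples)), 1)
  # silence mixes to the (normalized) original
  silent <- numeric(length(w1$samples))
  m0 <- mix_pair(w1, silent)
  expect_equal(m0$samples / max(abs(m0$samples)),
               w1$samples / max(abs(w1$samples)), tolerance = 1e-12)
  # both F0s visible: strong periodogram peaks at 200 and 251.98
  pg <- oracle_periodogram(mix$samples, 44100)
  peak_near <- function(f) max(pg$spec[abs(pg$freq - f) < 4])
  floor_level <- stats::median(pg$spec)
  expect_gt(peak_near(200) / floor_level, 100)
  expect_gt(peak_near(shift_f0(200, 4)) / floor_level, 100)
  # duration mismatch errors
  expect_error(mix_pair(w1, numeric(10)), "length")
})

test_that("token waveforms are deterministic given the spec", {
  a1 <- synthesize_vowel(vowel_spec("e", f0 = 200))
  a2 <- synthesize_vowel(vowel_spec("e", f0 = 200))
  expect_identical(a1$samples, a2$samples)
})
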