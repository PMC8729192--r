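# Harmonic/inharmonic complex-tone stimuli for the TFS1-style
# discrimination task: equal-amplitude random-phase partials, a fixed
# frequency shift delta_f for the inharmonic member, 5th-order
# Butterworth band-limiting around harmonics 9-13, and a pink-noise
# masker under both observation intervals.

#' Specification of one band-limited complex tone
#'
#' A harmonic complex (H) has partials at exact integer multiples of
#' `f0`; the inharmonic complex (I) shifts every partial up by the same
#' `delta_f`, destroying harmonicity while preserving component spacing
#' and the excitation pattern. Both pass the identical band-pass filter
#' with edges at `band[1]*f0` and `band[2]*f0`, so the only spectral
#' difference between H and I is the uniform shift.
#'
#' @param f0 fundamental frequency in Hz (default 100).
#' @param delta_f uniform upward component shift in Hz; 0 gives the
#'   harmonic complex.
#' @param n_components number of partials synthesized before filtering;
#'   the default 18 leaves stop-bands on both sides of the 9-13 band.
#' @param duration tone duration in seconds.
#' @param ramp raised-cosine on/off ramp in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param phase_seed seed for the random partial phases.
#' @param band ordered pair of harmonic ranks retained by the filter.
#' @return an object of class `complex_tone_spec`.
#' @export
complex_tone_spec <- function(f0 = 100, delta_f = 0, n_components = 18,
                              duration = 0.2, ramp = 0.02,
                              sample_rate = 44100, phase_seed = 1,
                              band = c(9, 13)) {
  stopifnot(f0 > 0, delta_f >= 0, n_components >= 1,
            band[1] < band[2], duration > 2 * ramp)
  if (sample_rate <= 2 * (band[2] * f0 + delta_f))
    stop("sample_rate must exceed twice the highest passband frequency")
  structure(list(f0 = f0, delta_f = delta_f, n_components = n_components,
                 duration = duration, ramp = ramp,
                 sample_rate = sample_rate, phase_seed = phase_seed,
                 band = band),
            class = "complex_tone_spec")
}

#' Synthesize an unfiltered equal-amplitude complex tone
#'
#' Sums `n_components` sinusoids at frequencies `k*f0 + delta_f`
#' (k = 1..n_components) with equal amplitudes and random phases drawn
#' from `phase_seed`, then applies the raised-cosine gate. Component
#' frequencies at or above Nyquist are an error, not silently dropped.
#'
#' @param spec a [complex_tone_spec()].
#' @return a `tone_signal`: list of `samples`, `sample_rate`, `label`
#'   ("H" if `delta_f == 0` else "I").
#' @export
synthesize_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_tone_spec"))
  freqs <- seq_len(spec$n_components) * spec$f0 + spec$delta_f
  if (max(freqs) >= spec$sample_rate / 2)
    stop("component frequency ", max(freqs),
         " Hz is at or above Nyquist (", spec$sample_rate / 2, " Hz)")
  phases <- with_seed(spec$phase_seed,
                      stats::runif(spec$n_components, 0, 2 * pi))
  n <- round(spec$duration * spec$sample_rate)
  t <- seq_len(n) / spec$sample_rate
  x <- numeric(n)
  for (k in seq_along(freqs))
    x <- x + sin(2 * pi * freqs[k] * t + phases[k])
  x <- apply_ramp(x, spec$ramp, spec$sample_rate)
  tone_signal(x, spec$sample_rate,
              label = if (spec$delta_f == 0) "H" else "I")
}

tone_signal <- function(samples, sample_rate, label = NA_character_) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 label = label), class = "tone_signal")
}

#' @export
print.tone_signal <- function(x, ...) {
  cat(sprintf("<tone_signal %s: %d samples @ %d Hz (%.0f ms), peak %.3f>\n",
              x$label, length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate,
              max(abs(x$samples))))
  invisible(x)
}

#' Band-limit a complex tone around its harmonic band
#'
#' Applies a 5th-order Butterworth band-pass with edges fixed at
#' `band[1]*f0` and `band[2]*f0` (900 and 1300 Hz at the defaults).
#' The edges never move with `delta_f`: harmonic and inharmonic tones
#' pass the identical filter, removing excitation-pattern cues. By
#' default the filter is run forward-backward (zero phase), doubling
#' the effective order; set `zero_phase = FALSE` for a single pass.
#'
#' @param tone a `tone_signal` from [synthesize_complex()].
#' @param spec the same [complex_tone_spec()] (supplies f0, band).
#' @param zero_phase logical; filter forward and backward.
#' @return the filtered, peak-normalized `tone_signal`.
#' @export
bandlimit <- function(tone, spec, zero_phase = TRUE) {
  stopifnot(inherits(tone, "tone_signal"),
            tone$sample_rate == spec$sample_rate)
  edges <- spec$band * spec$f0 / (spec$sample_rate / 2)
  bf <- signal::butter(5, edges, type = "pass")
  y <- if (zero_phase) signal::filtfilt(bf, tone$samples)
       else as.numeric(signal::filter(bf, tone$samples))
  tone_signal(peak_normalize(y), tone$sample_rate, tone$label)
}

#' Generate pink (1/f) noise
#'
#' Spectral-domain synthesis: Gaussian random spectrum shaped by
#' 1/sqrt(f) between `f_lo` and `f_hi`, zero outside, inverse FFT.
#' Power spectral density is proportional to 1/f across the shaped
#' band, i.e. equal energy per octave.
#'
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param seed RNG seed.
#' @param f_lo,f_hi band over which the 1/f spectrum extends, Hz.
#' @return a `tone_signal` with label "pink", unit RMS.
#' @export
pink_noise <- function(duration, sample_rate = 44100, seed = 1,
                       f_lo = 50, f_hi = 10000) {
  stopifnot(duration > 0, f_lo > 0, f_hi > f_lo,
            f_hi <= sample_rate / 2)
  n <- round(duration * sample_rate)
  nfft <- n
  freqs <- seq(0, sample_rate / 2, length.out = floor(nfft / 2) + 1)
  mag <- ifelse(freqs >= f_lo & freqs <= f_hi, 1 / sqrt(freqs), 0)
  ph <- with_seed(seed, stats::runif(length(freqs), 0, 2 * pi))
  half <- mag * exp(1i * ph)
  half[1] <- 0
  if (nfft %% 2 == 0) half[length(half)] <- Re(half[length(half)])
  spec_full <- c(half, Conj(rev(half[2:(length(half) - (nfft %% 2 == 0))])))
  x <- Re(stats::fft(spec_full, inverse = TRUE)) / nfft
  x <- x / rms(x)
  tone_signal(x[seq_len(n)], sample_rate, "pink")
}

#' Assemble one two-interval forced-choice trial
#'
#' The non-target interval is four harmonic tones in sequence (HHHH);
#' the target interval alternates harmonic and inharmonic (HIHI). Tones
#' within an interval are separated by `isi` seconds of silence and the
#' two intervals by `gap` seconds; the target occupies interval 1 or 2
#' at random. Pink noise is gated over the whole trial and mixed so its
#' spectrum level in the passband sits `noise_db` dB below the level of
#' one tone component.
#'
#' @param delta_f inharmonicity shift in Hz for the I tones.
#' @param config list of stimulus settings; see [trial_config()].
#' @param seed master seed for this trial (phases, noise, interval
#'   order are independent sub-streams).
#' @return a `trial_audio` object: `interval_1`, `interval_2` (lists of
#'   4 `tone_signal`s each), `target_interval`, `samples` (the full
#'   mixed trial waveform), `sample_rate`, `isi`, `gap`.
#' @export
build_trial <- function(delta_f, config = trial_config(), seed = 1) {
  stopifnot(delta_f >= 0)
  cfg <- config
  mk <- function(df, k) {
    sp <- complex_tone_spec(f0 = cfg$f0, delta_f = df,
                            n_components = cfg$n_components,
                            duration = cfg$tone_duration, ramp = cfg$ramp,
                            sample_rate = cfg$sample_rate,
                            phase_seed = substream(seed, paste0("phase", k)))
    bandlimit(synthesize_complex(sp), sp)
  }
  target_interval <- with_seed(substream(seed, "order"), sample(1:2, 1))
  # HIHI target: positions 2 and 4 carry the shifted tone
  target  <- lapply(1:4, function(k) mk(if (k %% 2 == 0) delta_f else 0, k))
  nontarg <- lapply(5:8, function(k) mk(0, k))
  iv1 <- if (target_interval == 1) target else nontarg
  iv2 <- if (target_interval == 2) target else nontarg
  sil <- function(sec) numeric(round(sec * cfg$sample_rate))
  seq_iv <- function(iv) {
    out <- iv[[1]]$samples
    for (k in 2:4) out <- c(out, sil(cfg$isi), iv[[k]]$samples)
    out
  }
  trial <- c(seq_iv(iv1), sil(cfg$gap), seq_iv(iv2))
  # component level in the passband: 5 equal components, peak-normalized
  # tone -> approximate per-component amplitude from the tone RMS
  n_band <- diff(cfg$band_ranks) + 1
  comp_pow <- rms(iv1[[1]]$samples)^2 / n_band
  noise <- pink_noise(length(trial) / cfg$sample_rate, cfg$sample_rate,
                      seed = substream(seed, "noise"))
  # pink PSD is c/f with total power c*log(f_hi/f_lo); pick c so the
  # spectrum level at the band centre sits noise_db below comp_pow
  f_mid <- mean(cfg$band_ranks) * cfg$f0
  c_target <- comp_pow * 10^(-cfg$noise_db / 10) * f_mid
  pwr <- c_target * log(10000 / 50)
  mixed <- trial + noise$samples * sqrt(pwr)
  structure(list(interval_1 = iv1, interval_2 = iv2,
                 target_interval = target_interval,
                 samples = peak_normalize(mixed),
                 sample_rate = cfg$sample_rate,
                 isi = cfg$isi, gap = cfg$gap, delta_f = delta_f),
            class = "trial_audio")
}

#' Stimulus configuration for TFS trials
#'
#' @param f0 fundamental, Hz.
#' @param tone_duration,ramp per-tone duration and raised-cosine ramp, s.
#' @param isi within-interval inter-stimulus interval, s.
#' @param gap between-interval gap, s.
#' @param sample_rate Hz.
#' @param n_components partials before filtering.
#' @param band_ranks harmonic ranks retained.
#' @param noise_db pink-noise spectrum level below per-component level, dB.
#' @return a list used by [build_trial()].
#' @export
trial_config <- function(f0 = 100, tone_duration = 0.2, ramp = 0.02,
                         isi = 0.1, gap = 0.5, sample_rate = 44100,
                         n_components = 18, band_ranks = c(9, 13),
                         noise_db = 15) {
  list(f0 = f0, tone_duration = tone_duration, ramp = ramp, isi = isi,
       gap = gap, sample_rate = sample_rate, n_components = n_components,
       band_ranks = band_ranks, noise_db = noise_db)
}

#' Expected duration in seconds of a trial built from a config
#' @param config see [trial_config()].
#' @return seconds.
#' @export
trial_duration <- function(config = trial_config()) {
  2 * (4 * config$tone_duration + 3 * config$isi) + config$gap
}
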