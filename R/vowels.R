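# Klatt-style cascade formant synthesis of the five steady-state
# vowels /a, i, e, u, o/ and construction of concurrent vowel pairs
# separated by 0, 1, 2 or 4 semitones of F0.

#' Default formant table for the five steady-state vowels
#'
#' Centre frequencies and bandwidths (Hz) of F1-F4 for /a, i, e, u, o/,
#' standard steady-state values in the Peterson & Barney tradition.
#' Override any entry via the `formants` argument of [vowel_spec()].
#'
#' @return named list; each element a 4x2 matrix (columns `freq`, `bw`).
#' @export
default_formants <- function() {
  mk <- function(f, b) {
    m <- cbind(freq = f, bw = b)
    rownames(m) <- paste0("F", 1:4)
    m
  }
  list(a = mk(c(750, 1200, 2500, 3400), c(90, 110, 170, 250)),
       i = mk(c(280, 2250, 3000, 3700), c(60, 100, 150, 200)),
       e = mk(c(480, 1900, 2650, 3500), c(70, 100, 160, 220)),
       u = mk(c(320, 900, 2300, 3200), c(70, 110, 150, 200)),
       o = mk(c(450, 850, 2600, 3300), c(80, 100, 160, 220)))
}

#' Specification of one steady-state synthetic vowel
#'
#' @param identity one of `"a" "i" "e" "u" "o"`.
#' @param f0 fundamental frequency, Hz (base value 200).
#' @param formants 4x2 matrix of formant centres and bandwidths; by
#'   default taken from [default_formants()].
#' @param duration seconds (default 0.270).
#' @param ramp raised-cosine onset/offset, seconds (default 0.020).
#' @param sample_rate Hz.
#' @return an object of class `vowel_spec`.
#' @export
vowel_spec <- function(identity, f0 = 200, formants = NULL,
                       duration = 0.270, ramp = 0.020,
                       sample_rate = 44100) {
  identity <- match.arg(identity, c("a", "i", "e", "u", "o"))
  if (is.null(formants)) formants <- default_formants()[[identity]]
  stopifnot(f0 > 0, duration > 2 * ramp,
            all(diff(formants[, "freq"]) > 0))
  structure(list(identity = identity, f0 = f0, formants = formants,
                 duration = duration, ramp = ramp,
                 sample_rate = sample_rate),
            class = "vowel_spec")
}

#' Shift a fundamental frequency by a number of semitones
#'
#' A semitone is a frequency ratio of 2^(1/12).
#'
#' @param base frequency in Hz.
#' @param semitones shift (may be fractional or negative).
#' @return shifted frequency in Hz.
#' @export
shift_f0 <- function(base, semitones) {
  stopifnot(all(base > 0))
  base * 2^(semitones / 12)
}

# One Klatt digital resonator: y[n] = A x[n] + B y[n-1] + C y[n-2]
# with C = -exp(-2 pi bw T), B = 2 exp(-pi bw T) cos(2 pi f T),
# A = 1 - B - C (unity gain at DC).
klatt_resonator <- function(x, f, bw, sample_rate) {
  T <- 1 / sample_rate
  C <- -exp(-2 * pi * bw * T)
  B <- 2 * exp(-pi * bw * T) * cos(2 * pi * f * T)
  A <- 1 - B - C
  as.numeric(signal::filter(signal::Arma(b = A, a = c(1, -B, -C)), x))
}

#' Synthesize a steady-state vowel with a cascade formant synthesizer
#'
#' A glottal impulse train at `f0` drives a serial cascade of four
#' second-order (Klatt) resonators at the specified formant centres and
#' bandwidths, followed by a raised-cosine gate and peak normalization.
#' Steady-state vowels only: no aspiration or frication branches.
#'
#' @param spec a [vowel_spec()].
#' @return a `tone_signal` labelled with the vowel identity.
#' @export
synthesize_vowel <- function(spec) {
  stopifnot(inherits(spec, "vowel_spec"))
  if (max(spec$formants[, "freq"]) >= spec$sample_rate / 2)
    stop("formant centre above Nyquist")
  n <- round(spec$duration * spec$sample_rate)
  # impulse train: one pulse per glottal period, fractional periods
  # accumulated so mean rate is exactly f0
  period <- spec$sample_rate / spec$f0
  pulses <- round(seq(1, n, by = period))
  pulses <- pulses[pulses <= n]
  x <- numeric(n)
  x[pulses] <- 1
  # -6 dB/oct source tilt approximating the glottal spectrum
  x <- as.numeric(signal::filter(signal::Arma(b = 1, a = c(1, -0.98)), x))
  for (k in seq_len(nrow(spec$formants)))
    x <- klatt_resonator(x, spec$formants[k, "freq"],
                         spec$formants[k, "bw"], spec$sample_rate)
  x <- apply_ramp(x - mean(x), spec$ramp, spec$sample_rate)
  tone_signal(peak_normalize(x), spec$sample_rate, spec$identity)
}

#' Enumerate the vowel token set across F0 conditions
#'
#' One token per (identity x F0 condition); F0 conditions are the base
#' F0 plus each listed semitone shift. Five identities with shifts
#' {1, 2, 4} on top of the base give the full 20-token set.
#'
#' @param base_f0 base fundamental, Hz.
#' @param shifts semitone shifts added to the base (the base itself is
#'   always included as shift 0).
#' @param identities vowel identities to include.
#' @param ... passed to [vowel_spec()] (duration, sample_rate, ...).
#' @return data frame of tokens: identity, shift_semitones, f0, and a
#'   list-column `spec` of [vowel_spec()] objects.
#' @export
enumerate_tokens <- function(base_f0 = 200, shifts = c(1, 2, 4),
                             identities = c("a", "i", "e", "u", "o"),
                             ...) {
  stopifnot(length(identities) >= 1)
  all_shifts <- unique(c(0, shifts))
  grid <- expand.grid(identity = identities, shift = all_shifts,
                      stringsAsFactors = FALSE)
  grid$f0 <- shift_f0(base_f0, grid$shift)
  grid$spec <- lapply(seq_len(nrow(grid)), function(i)
    vowel_spec(grid$identity[i], f0 = grid$f0[i], ...))
  names(grid)[2] <- "shift_semitones"
  grid
}

#' Enumerate concurrent vowel pairs across F0-difference conditions
#'
#' All unordered pairs of distinct identities at each semitone
#' difference; one member at the base F0, the other shifted by the
#' condition's semitone difference. The same identity never appears
#' twice in a pair, even at different F0s. Which identity takes the
#' shifted F0 alternates deterministically across pairs.
#'
#' @param tokens output of [enumerate_tokens()].
#' @param diffs semitone differences (default 0, 1, 2, 4).
#' @return data frame: pair_id, vowel_1, vowel_2, semitone_diff, f0_1,
#'   f0_2 (vowel_1 carries f0 as assigned by the alternation rule).
#' @export
enumerate_pairs <- function(tokens, diffs = c(0, 1, 2, 4)) {
  identities <- unique(tokens$identity)
  base_f0 <- min(tokens$f0)
  stopifnot(length(identities) >= 2)
  combs <- utils::combn(identities, 2)
  out <- do.call(rbind, lapply(diffs, function(d) {
    stopifnot(d == 0 || d %in% tokens$shift_semitones)
    df <- data.frame(vowel_1 = combs[1, ], vowel_2 = combs[2, ],
                     semitone_diff = d, stringsAsFactors = FALSE)
    # alternate which member is shifted
    hi <- shift_f0(base_f0, d)
    alt <- seq_len(nrow(df)) %% 2 == 0
    df$f0_1 <- ifelse(alt, hi, base_f0)
    df$f0_2 <- ifelse(alt, base_f0, hi)
    df
  }))
  out$pair_id <- seq_len(nrow(out))
  out[, c("pair_id", "vowel_1", "vowel_2", "semitone_diff", "f0_1", "f0_2")]
}

#' Mix a concurrent vowel pair into one waveform
#'
#' The two members are RMS-equalized (0 dB member-to-member ratio),
#' summed sample-wise, and peak-normalized.
#'
#' @param wave_1,wave_2 numeric waveforms or `tone_signal`s of equal
#'   length and rate.
#' @return a `tone_signal` labelled `"mix"`.
#' @export
mix_pair <- function(wave_1, wave_2) {
  sr <- NULL
  get_samples <- function(w) {
    if (inherits(w, "tone_signal")) { sr <<- sr %||% w$sample_rate; w$samples }
    else w
  }
  x1 <- get_samples(wave_1); x2 <- get_samples(wave_2)
  if (length(x1) != length(x2))
    stop("pair members differ in length (", length(x1), " vs ",
         length(x2), " samples)")
  r1 <- rms(x1); r2 <- rms(x2)
  if (r1 > 0) x1 <- x1 / r1
  if (r2 > 0) x2 <- x2 / r2
  if (r1 == 0) return(tone_signal(peak_normalize(x2), sr %||% 44100, "mix"))
  if (r2 == 0) return(tone_signal(peak_normalize(x1), sr %||% 44100, "mix"))
  tone_signal(peak_normalize(x1 + x2), sr %||% 44100, "mix")
}

#' Synthesize the mixed waveform of one enumerated pair
#'
#' @param pair one row of [enumerate_pairs()] output.
#' @param ... passed to [vowel_spec()].
#' @return a `tone_signal` of the RMS-equalized mix.
#' @export
synthesize_pair <- function(pair, ...) {
  w1 <- synthesize_vowel(vowel_spec(pair$vowel_1, f0 = pair$f0_1, ...))
  w2 <- synthesize_vowel(vowel_spec(pair$vowel_2, f0 = pair$f0_2, ...))
  mix_pair(w1, w2)
}
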