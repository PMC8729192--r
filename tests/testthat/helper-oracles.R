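# Independent oracles used across the suite. These deliberately avoid
# the package's own signal path: spectra come from stats::spec.pgram,
# F0 from autocorrelation, formants from LPC root-solving on a
# decimated signal, and the mixed ANOVA from stats::aov with an Error
# stratum.

# Raw periodogram of a waveform.
oracle_periodogram <- function(x, sample_rate, spans = NULL) {
  pg <- stats::spec.pgram(stats::ts(x, frequency = sample_rate),
                          spans = spans, taper = 0, plot = FALSE,
                          detrend = FALSE)
  list(freq = pg$freq, spec = pg$spec)
}

# Fraction of total power inside [f_lo, f_hi].
oracle_band_fraction <- function(x, sample_rate, f_lo, f_hi) {
  pg <- oracle_periodogram(x, sample_rate)
  sel <- pg$freq >= f_lo & pg$freq <= f_hi
  sum(pg$spec[sel]) / sum(pg$spec)
}

# Log-log slope of a smoothed PSD between f_lo and f_hi.
oracle_psd_slope <- function(x, sample_rate, f_lo, f_hi) {
  pg <- oracle_periodogram(x, sample_rate, spans = 101)
  sel <- pg$freq >= f_lo & pg$freq <= f_hi
  unname(stats::coef(stats::lm(log10(pg$spec[sel]) ~
                                 log10(pg$freq[sel])))[2])
}

# Exact single-frequency DFT probe: amplitude of the sinusoidal
# component at f Hz (immune to periodogram padding/leakage griding).
oracle_component_amp <- function(x, sample_rate, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}

# Autocorrelation-based F0 estimate searching lags for [f_min, f_max].
oracle_f0 <- function(x, sample_rate, f_min = 80, f_max = 400) {
  lag_min <- floor(sample_rate / f_max)
  lag_max <- ceiling(sample_rate / f_min)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  sample_rate / (which.max(ac[lag_min:lag_max]) + lag_min - 1)
}

# Spectral-envelope formant estimate: sample the DFT amplitude at the
# harmonics of f0 and return the frequencies of the local envelope
# maxima (granularity f0, adequate to confirm resonance placement; LPC
# root-finding locks onto individual harmonics at f0 = 200 Hz).
oracle_formants <- function(x, sample_rate, f0, n_formants = 2,
                            f_max = 4000) {
  h <- seq(f0, f_max, by = f0)
  a <- vapply(h, function(f) oracle_component_amp(x, sample_rate, f),
              numeric(1))
  a <- a * h # undo the -6 dB/oct source tilt so peaks mark resonances
  n <- length(a)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else a[i - 1]
    right <- if (i == n) -Inf else a[i + 1]
    a[i] > left && a[i] > right
  }, logical(1))
  h[is_peak][seq_len(n_formants)]
}

# Mixed between x within ANOVA through stats::aov (Error stratum) on a
# cohort-shaped table; returns the three F statistics.
oracle_rm_anova <- function(table, dv = paste0("cvi_", c(0, 1, 2, 4), "st")) {
  long <- stats::reshape(as.data.frame(table)[, c("child_id", "group", dv)],
                         varying = list(dv), v.names = "y",
                         timevar = "cond", times = dv,
                         direction = "long")
  long$cond <- factor(long$cond)
  long$child_id <- factor(long$child_id)
  long$group <- factor(long$group)
  fit <- stats::aov(y ~ group * cond + Error(child_id),
                    data = long)
  s <- summary(fit)
  between <- s[["Error: child_id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(F_between = between["group", "F value"],
       F_within = within["cond", "F value"],
       F_interaction = within["group:cond", "F value"])
}

# A cohort-shaped random fixture (balanced, complete) without going
# through the simulation pipeline.
random_cohort_fixture <- function(n_per_group = 15, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  out <- data.frame(
    child_id = sprintf("S%02d", 1:n),
    group = rep(c("RD", "TD"), each = n_per_group),
    tfs_percent = pmin(pmax(rnorm(n, 70, 12), 0), 100))
  for (col in paste0("cvi_", c(0, 1, 2, 4), "st"))
    out[[col]] <- pmin(pmax(rnorm(n, 80, 8), 0), 100)
  out
}

# Deterministic observer: correct iff delta_f at or above a threshold.
threshold_observer <- function(threshold) function(delta_f) delta_f >= threshold
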