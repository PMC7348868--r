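#' Acoustic feature extraction configuration
#'
#' Collects every tunable of the 36-feature frame extractor. Frames are
#' 10 ms with no overlap; cepstra use 32 bands and 14 coefficients
#' (including the 0th); pitch and HNR use a longer analysis context centred
#' on each 10 ms hop because a 10 ms frame cannot hold a full period of a
#' low male f0.
#'
#' @param frame_ms analysis window length in ms (no overlap).
#' @param n_bands number of mel / gammatone filterbank bands.
#' @param n_cep number of cepstral coefficients kept (incl. the 0th).
#' @param mel_fmin,mel_fmax mel filterbank frequency span, Hz.
#' @param erb_fmin,erb_fmax gammatone (ERB-spaced) filterbank span, Hz.
#' @param log_floor floor applied to filterbank energies before log.
#' @param rolloff_pct spectral rolloff threshold k, percent of total power.
#' @param f0_min,f0_max pitch search range, Hz.
#' @param pitch_context_ms pitch/HNR analysis context length, ms.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced (below it pitch is undefined).
#' @param energy_eps frames with |mean| below this have signal energy
#'   (sigma/mu) undefined.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(frame_ms = 10, n_bands = 32L, n_cep = 14L,
                           mel_fmin = 0, mel_fmax = 8000,
                           erb_fmin = 50, erb_fmax = 8000,
                           log_floor = 1e-10, rolloff_pct = 95,
                           f0_min = 60, f0_max = 400,
                           pitch_context_ms = 40,
                           voicing_threshold = 0.3,
                           energy_eps = 1e-12) {
  structure(list(frame_ms = frame_ms, n_bands = as.integer(n_bands),
                 n_cep = as.integer(n_cep), mel_fmin = mel_fmin,
                 mel_fmax = mel_fmax, erb_fmin = erb_fmin,
                 erb_fmax = erb_fmax, log_floor = log_floor,
                 rolloff_pct = rolloff_pct, f0_min = f0_min, f0_max = f0_max,
                 pitch_context_ms = pitch_context_ms,
                 voicing_threshold = voicing_threshold,
                 energy_eps = energy_eps),
            class = "feature_config")
}

#' Base (per-frame) feature names, in canonical order
#'
#' Order: pitch, hnr, zcr, mfcc_1..14, gtcc_1..14, mean_freq, median_freq,
#' energy, centroid, rolloff. `mfcc_1`/`gtcc_1` denote the 0th DCT
#' coefficient (the count of 14 includes it).
#'
#' @param n_cep number of cepstral coefficients.
#' @return character vector of 36 names (for the default `n_cep = 14`).
#' @export
feature_names_base <- function(n_cep = 14L) {
  c("pitch", "hnr", "zcr",
    paste0("mfcc_", seq_len(n_cep)), paste0("gtcc_", seq_len(n_cep)),
    "mean_freq", "median_freq", "energy", "centroid", "rolloff")
}

#' Session-level feature names (108), in canonical order
#'
#' For each base feature in Table-order, its mean, median and SD summary,
#' named `mean_<f>`, `median_<f>`, `sd_<f>`.
#'
#' @param n_cep number of cepstral coefficients.
#' @return character vector of 108 names for the default configuration.
#' @export
feature_names_summary <- function(n_cep = 14L) {
  base <- feature_names_base(n_cep)
  as.vector(vapply(base, function(f) paste0(c("mean_", "median_", "sd_"), f),
                   character(3)))
}

#' Slice a signal into non-overlapping 10 ms frames
#'
#' Frame length is `round(frame_ms/1000 * rate)` samples; the trailing
#' partial frame is dropped.
#'
#' @param signal an [audio_signal()].
#' @param frame_ms frame length in milliseconds.
#' @return numeric matrix with one column per frame (N rows).
#' @export
frame_signal <- function(signal, frame_ms = 10) {
  n <- round(frame_ms / 1000 * signal$rate)
  if (n < 1) stop("frame shorter than one sample")
  nf <- length(signal$samples) %/% n
  if (nf < 1) stop("signal shorter than one frame")
  matrix(signal$samples[seq_len(n * nf)], nrow = n, ncol = nf)
}

#' Zero-crossing rate of a frame
#'
#' \deqn{ZCR(X) = \frac{1}{2N} \sum_i |sgn(X_i) - sgn(X_{i-1})|}
#' with sgn(0) = 0; the sum runs over consecutive sample pairs.
#'
#' @param frame numeric vector of samples.
#' @return dimensionless rate in \code{[0, 1]}.
#' @export
zcr <- function(frame) {
  stopifnot(length(frame) >= 2L)
  sum(abs(diff(sign(frame)))) / (2 * length(frame))
}

#' Signal energy of a frame: sigma/mu
#'
#' Coefficient-of-variation form printed in the feature table: sample
#' standard deviation divided by the mean. Near-zero-mean frames have no
#' defined value and return NA (excluded from session summaries).
#'
#' @param frame numeric vector of samples.
#' @param eps |mean| threshold below which the value is undefined.
#' @return dimensionless value, or NA.
#' @export
signal_energy <- function(frame, eps = 1e-12) {
  m <- mean(frame)
  if (abs(m) < eps) return(NA_real_)
  stats::sd(frame) / m
}

#' One-sided power spectrum of a frame
#'
#' Periodogram |FFT|^2 / N folded to one side (interior bins doubled) so
#' that the total equals the time-domain energy sum(x^2) (Parseval).
#'
#' @param frame numeric vector of N samples.
#' @param rate sampling rate in Hz.
#' @return list with `freq` (Hz per bin) and `power` (spectral values).
#' @export
spectrum_of <- function(frame, rate) {
  n <- length(frame)
  stopifnot(n >= 2L)
  p <- Mod(stats::fft(frame))^2 / n
  half <- floor(n / 2) + 1L
  one <- p[seq_len(half)]
  if (n %% 2 == 0) {
    if (half > 2L) one[2:(half - 1L)] <- 2 * one[2:(half - 1L)]
  } else {
    one[2:half] <- 2 * one[2:half]
  }
  list(freq = (seq_len(half) - 1L) * rate / n, power = one)
}

#' Power-weighted mean frequency
#' @param sp spectrum from [spectrum_of()].
#' @return Hz.
#' @export
mean_frequency <- function(sp) {
  tot <- sum(sp$power)
  if (tot <= 0) stop("all-zero spectrum")
  sum(sp$freq * sp$power) / tot
}

#' Median frequency of the power spectrum
#'
#' Frequency of the first bin at which cumulative power reaches half the
#' total ("first bin reaching >= 50%" rule).
#'
#' @param sp spectrum from [spectrum_of()].
#' @return Hz.
#' @export
median_frequency <- function(sp) {
  tot <- sum(sp$power)
  if (tot <= 0) stop("all-zero spectrum")
  sp$freq[which(cumsum(sp$power) >= tot / 2)[1]]
}

#' Spectral centroid
#'
#' \deqn{c = \sum_{i=b_1}^{b_2} f_i s_i / \sum_{i=b_1}^{b_2} s_i}
#'
#' @param sp spectrum from [spectrum_of()].
#' @param b1,b2 band edges as bin indices (default: full band).
#' @return Hz.
#' @export
spectral_centroid <- function(sp, b1 = 1L, b2 = length(sp$power)) {
  s <- sp$power[b1:b2]
  tot <- sum(s)
  if (tot <= 0) stop("zero spectral mass in band")
  sum(sp$freq[b1:b2] * s) / tot
}

#' Spectral rolloff point
#'
#' Smallest bin frequency r such that the cumulative spectral value from b1
#' reaches k percent of the band total.
#'
#' @param sp spectrum from [spectrum_of()].
#' @param k rolloff threshold in percent, in (0, 100].
#' @param b1,b2 band edges as bin indices.
#' @return Hz.
#' @export
spectral_rolloff <- function(sp, k = 95, b1 = 1L, b2 = length(sp$power)) {
  stopifnot(k > 0, k <= 100)
  s <- sp$power[b1:b2]
  tot <- sum(s)
  if (tot <= 0) stop("zero spectral mass in band")
  idx <- which(cumsum(s) >= (k / 100) * tot - 1e-12 * tot)[1]
  sp$freq[b1:b2][idx]
}

# mel and ERB auxiliary scales
.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
.hz_to_erbrate <- function(f) 21.4 * log10(1 + 0.00437 * f)
.erbrate_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# Triangular mel filterbank sampled at FFT bin frequencies (rows sum to 1).
.mel_filterbank <- function(freqs, n_bands, fmin, fmax) {
  edges <- .mel_to_hz(seq(.hz_to_mel(fmin), .hz_to_mel(fmax),
                          length.out = n_bands + 2L))
  fb <- matrix(0, n_bands, length(freqs))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; ce <- edges[b + 1L]; hi <- edges[b + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb / pmax(rowSums(fb), .Machine$double.eps)
}

# Frequency-sampled 4th-order gammatone magnitude-squared responses at
# ERB-spaced centre frequencies (rows sum to 1).
.gammatone_filterbank <- function(freqs, n_bands, fmin, fmax) {
  cfs <- .erbrate_to_hz(seq(.hz_to_erbrate(fmin), .hz_to_erbrate(fmax),
                            length.out = n_bands))
  fb <- matrix(0, n_bands, length(freqs))
  for (b in seq_len(n_bands)) {
    bw <- 1.019 * 24.7 * (4.37 * cfs[b] / 1000 + 1)
    fb[b, ] <- (1 + ((freqs - cfs[b]) / bw)^2)^(-4)
  }
  fb / rowSums(fb)
}

# Orthonormal DCT-II matrix (n_cep x n_bands).
.dct_matrix <- function(n_cep, n_bands) {
  k <- seq_len(n_cep) - 1L
  n <- seq_len(n_bands) - 1L
  d <- sqrt(2 / n_bands) * cos(pi * outer(k, n + 0.5) / n_bands)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

# Filterbank log-energies -> cepstra for a matrix of one-sided power
# spectra (bins x frames).
.cepstra <- function(pow, fb, dct, log_floor) {
  dct %*% log(pmax(fb %*% pow, log_floor))
}

#' Mel-frequency cepstral coefficients of one frame
#'
#' Hamming-windowed power spectrum -> triangular mel filterbank ->
#' log (floored) -> orthonormal DCT-II; the first `n_cep` coefficients
#' (including the 0th) are returned.
#'
#' @param frame numeric vector of samples.
#' @param rate sampling rate, Hz.
#' @param config a [feature_config()].
#' @return numeric vector of `config$n_cep` coefficients.
#' @export
mfcc14 <- function(frame, rate, config = feature_config()) {
  .frame_cepstra(frame, rate, config, type = "mel")
}

#' Gammatone cepstral coefficients of one frame
#'
#' As [mfcc14()] but with an ERB-spaced gammatone filterbank.
#'
#' @inheritParams mfcc14
#' @return numeric vector of `config$n_cep` coefficients.
#' @export
gtcc14 <- function(frame, rate, config = feature_config()) {
  .frame_cepstra(frame, rate, config, type = "gammatone")
}

.frame_cepstra <- function(frame, rate, config, type) {
  n <- length(frame)
  sp <- spectrum_of(frame * .hamming(n), rate)
  fb <- if (type == "mel") {
    .mel_filterbank(sp$freq, config$n_bands, config$mel_fmin, config$mel_fmax)
  } else {
    .gammatone_filterbank(sp$freq, config$n_bands, config$erb_fmin,
                          config$erb_fmax)
  }
  dct <- .dct_matrix(config$n_cep, config$n_bands)
  as.vector(.cepstra(matrix(sp$power, ncol = 1), fb, dct, config$log_floor))
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Pitch and harmonics-to-noise ratio of an analysis context
#'
#' Normalized-autocorrelation method: the peak r_max of r(tau) =
#' ac(tau)/ac(0) of the mean-removed context over lags corresponding to
#' `[f0_min, f0_max]` gives pitch = rate/lag (undefined when r_max falls
#' below the voicing threshold) and HNR = 10 log10(r_max / (1 - r_max)) dB.
#'
#' @param context numeric vector, at least two periods of `f0_min` long.
#' @param rate sampling rate, Hz.
#' @param config a [feature_config()].
#' @return list with `pitch` (Hz or NA) and `hnr` (dB or NA).
#' @export
pitch_hnr <- function(context, rate, config = feature_config()) {
  x <- context - mean(context)
  n <- length(x)
  lag_min <- max(2L, floor(rate / config$f0_max))
  lag_max <- min(n - 1L, ceiling(rate / config$f0_min))
  if (lag_max <= lag_min) stop("context too short for the pitch range")
  e0 <- sum(x^2)
  if (e0 <= 0) return(list(pitch = NA_real_, hnr = NA_real_))
  nfft <- 2^ceiling(log2(n + lag_max + 1L))
  fx <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(Conj(fx) * fx, inverse = TRUE)) / nfft
  lags <- lag_min:lag_max
  # unbiased normalization: the zero-padded estimate shrinks by (n-lag)/n
  r <- ac[lags + 1L] / ac[1L] * (n / (n - lags))
  # smallest lag within tolerance of the global peak, avoiding octave
  # (subharmonic) errors where multiples of the period tie
  i <- which(r >= max(r) - 0.01)[1]
  rmax <- min(max(r[i], 1e-6), 1 - 1e-6)
  pitch <- if (r[i] >= config$voicing_threshold) rate / (lag_min + i - 1L)
           else NA_real_
  list(pitch = pitch, hnr = 10 * log10(rmax / (1 - rmax)))
}

#' Per-frame feature matrix for a whole session
#'
#' Vectorized extractor computing all 36 per-frame features of the canonical
#' list ([feature_names_base()]) on non-overlapping 10 ms frames. Pitch and
#' HNR use a 40 ms context centred on each frame (hop stays 10 ms so the
#' frame count matches the other features). Undefined values (unvoiced
#' pitch, zero-mean energy, silent-frame spectral moments) are NA.
#'
#' @param signal an [audio_signal()] (normally preprocessed).
#' @param config a [feature_config()].
#' @return numeric matrix, frames x 36, with feature column names.
#' @export
extract_frame_features <- function(signal, config = feature_config()) {
  rate <- signal$rate
  fm <- frame_signal(signal, config$frame_ms)
  n <- nrow(fm); nf <- ncol(fm)
  out <- matrix(NA_real_, nf, 3L + 2L * config$n_cep + 5L)
  colnames(out) <- feature_names_base(config$n_cep)

  # --- temporal features ---
  sg <- sign(fm)
  out[, "zcr"] <- colSums(abs(sg[-1L, , drop = FALSE] -
                              sg[-n, , drop = FALSE])) / (2 * n)
  mu <- colMeans(fm)
  sdev <- sqrt(colSums((fm - rep(mu, each = n))^2) / (n - 1L))
  en <- ifelse(abs(mu) < config$energy_eps, NA_real_, sdev / mu)
  out[, "energy"] <- en

  # --- spectral moments on the unwindowed periodogram ---
  half <- floor(n / 2) + 1L
  P <- Mod(stats::mvfft(fm))^2 / n
  P <- P[seq_len(half), , drop = FALSE]
  if (n %% 2 == 0 && half > 2L) {
    P[2:(half - 1L), ] <- 2 * P[2:(half - 1L), ]
  } else if (n %% 2 == 1) {
    P[2:half, ] <- 2 * P[2:half, ]
  }
  freqs <- (seq_len(half) - 1L) * rate / n
  tot <- colSums(P)
  ok <- tot > 0
  ctr <- colSums(P * freqs) / ifelse(ok, tot, NA_real_)
  out[ok, "mean_freq"] <- ctr[ok]
  out[ok, "centroid"] <- ctr[ok]
  cs <- apply(P, 2, cumsum)
  med_i <- max.col(t(cs >= rep(tot / 2, each = half)), ties.method = "first")
  rol_i <- max.col(t(cs >= rep((config$rolloff_pct / 100) * tot -
                                 1e-12 * tot, each = half)),
                   ties.method = "first")
  out[ok, "median_freq"] <- freqs[med_i[ok]]
  out[ok, "rolloff"] <- freqs[rol_i[ok]]

  # --- cepstra on the Hamming-windowed periodogram ---
  Pw <- Mod(stats::mvfft(fm * .hamming(n)))^2 / n
  Pw <- Pw[seq_len(half), , drop = FALSE]
  if (n %% 2 == 0 && half > 2L) {
    Pw[2:(half - 1L), ] <- 2 * Pw[2:(half - 1L), ]
  } else if (n %% 2 == 1) {
    Pw[2:half, ] <- 2 * Pw[2:half, ]
  }
  dct <- .dct_matrix(config$n_cep, config$n_bands)
  melfb <- .mel_filterbank(freqs, config$n_bands, config$mel_fmin,
                           config$mel_fmax)
  gtfb <- .gammatone_filterbank(freqs, config$n_bands, config$erb_fmin,
                                config$erb_fmax)
  out[, paste0("mfcc_", seq_len(config$n_cep))] <-
    t(.cepstra(Pw, melfb, dct, config$log_floor))
  out[, paste0("gtcc_", seq_len(config$n_cep))] <-
    t(.cepstra(Pw, gtfb, dct, config$log_floor))

  # --- pitch / HNR on centred contexts ---
  ph <- .batch_pitch_hnr(signal$samples, rate, nf, n, config)
  out[, "pitch"] <- ph$pitch
  out[, "hnr"] <- ph$hnr
  out
}

# Vectorized pitch/HNR: one FFT-based autocorrelation per frame context.
.batch_pitch_hnr <- function(samples, rate, nf, frame_n, config) {
  ctx <- round(config$pitch_context_ms / 1000 * rate)
  len <- length(samples)
  ctx <- min(ctx, len)
  centers <- (seq_len(nf) - 1L) * frame_n + frame_n / 2
  starts <- pmin(pmax(1L, round(centers - ctx / 2)), len - ctx + 1L)
  X <- matrix(samples[outer(seq_len(ctx) - 1L, starts, "+")], ctx, nf)
  X <- X - rep(colMeans(X), each = ctx)
  lag_min <- max(2L, floor(rate / config$f0_max))
  lag_max <- min(ctx - 1L, ceiling(rate / config$f0_min))
  if (lag_max <= lag_min) stop("pitch context too short for the f0 range")
  nfft <- 2^ceiling(log2(ctx + lag_max + 1L))
  FX <- stats::mvfft(rbind(X, matrix(0, nfft - ctx, nf)))
  ac <- Re(stats::mvfft(Conj(FX) * FX, inverse = TRUE)) / nfft
  e0 <- ac[1L, ]
  lags <- lag_min:lag_max
  r <- ac[lags + 1L, , drop = FALSE] /
    rep(ifelse(e0 > 0, e0, NA_real_), each = length(lags)) *
    (ctx / (ctx - lags))
  # smallest lag within tolerance of the per-frame peak (octave guard)
  peak <- apply(r, 2, max)
  arg <- max.col(t(r >= rep(peak - 0.01, each = length(lags))),
                 ties.method = "first")
  rmax <- r[cbind(arg, seq_len(nf))]
  voiced <- !is.na(rmax) & rmax >= config$voicing_threshold
  pitch <- ifelse(voiced, rate / (lag_min + arg - 1L), NA_real_)
  rcl <- pmin(pmax(rmax, 1e-6), 1 - 1e-6)
  hnr <- ifelse(is.na(rmax), NA_real_, 10 * log10(rcl / (1 - rcl)))
  list(pitch = pitch, hnr = hnr)
}

#' Summarize frame features into the 108-dimension session vector
#'
#' Mean, median and sample SD per base feature, computed over frames where
#' the feature is defined; NA frames are excluded rather than zero-filled.
#'
#' @param frame_features frames x 36 matrix from [extract_frame_features()].
#' @return named numeric vector of length 108 ([feature_names_summary()]
#'   order).
#' @export
summarize_features <- function(frame_features) {
  stopifnot(is.matrix(frame_features))
  base <- colnames(frame_features)
  out <- numeric(3L * length(base))
  names(out) <- as.vector(vapply(base, function(f)
    paste0(c("mean_", "median_", "sd_"), f), character(3)))
  for (j in seq_along(base)) {
    v <- frame_features[, j]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("feature '", base[j], "' undefined in (nearly) all frames")
    out[3L * j - 2L] <- mean(v)
    out[3L * j - 1L] <- stats::median(v)
    out[3L * j] <- stats::sd(v)
  }
  out
}

#' Extract the 108 session features from a raw signal
#'
#' Convenience wrapper: [preprocess_audio()] then
#' [extract_frame_features()] then [summarize_features()].
#'
#' @param signal an [audio_signal()].
#' @param config a [feature_config()].
#' @param preprocess run the waveform preprocessing chain first (default).
#' @return named numeric vector of length 108.
#' @export
extract_features <- function(signal, config = feature_config(),
                             preprocess = TRUE) {
  if (preprocess) signal <- preprocess_audio(signal)$signal
  summarize_features(extract_frame_features(signal, config))
}
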