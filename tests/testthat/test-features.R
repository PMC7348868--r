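test_that("framing tiles the signal in 10 ms blocks, dropping the tail", {
  rate <- 16000
  expect_equal(ncol(frame_signal(audio_signal(numeric(1600) + 1, rate))), 10)
  expect_equal(ncol(frame_signal(audio_signal(numeric(1650) + 1, rate))), 10)
  expect_equal(nrow(frame_signal(audio_signal(numeric(1600) + 1, rate))), 160)
  # 600 s at 16 kHz gives 60,000 frames by the same exact formula
  expect_equal((600 * rate) %/% round(0.010 * rate), 60000)
  expect_error(frame_signal(audio_signal(numeric(100) + 1, rate)), "shorter")
})

test_that("zero-crossing rate follows the signum-difference formula", {
  expect_equal(zcr(c(2, 5, 1, 3)), 0)
  expect_equal(zcr(c(1, -1, 1, 1)), 0.5)
  expect_equal(zcr(rep(c(1, -1), 80)), 159 / 160)
  # sgn(0) = 0 contributes half steps
  expect_equal(zcr(c(1, 0, -1)), (1 + 1) / 6)
})

test_that("signal energy is sample SD over mean, guarded near zero mean", {
  expect_equal(signal_energy(rep(2, 10)), 0)
  expect_equal(signal_energy(c(1, 3)), sqrt(2) / 2)
  expect_true(is.na(signal_energy(c(-1, 1))))
})

test_that("power spectrum satisfies Parseval and locates pure tones", {
  rate <- 16000
  fr <- sin(2 * pi * 1000 * (0:159) / rate)
  sp <- spectrum_of(fr, rate)
  expect_equal(sp$freq[which.max(sp$power)], 1000)
  x <- local_seed(6, rnorm(160))
  sp2 <- spectrum_of(x, rate)
  expect_equal(sum(sp2$power), sum(x^2), tolerance = 1e-10)
})

test_that("spectral moments match their definitions on crafted spectra", {
  one_bin <- list(freq = c(0, 1000, 2000, 3000), power = c(0, 5, 0, 0))
  expect_equal(mean_frequency(one_bin), 1000)
  expect_equal(median_frequency(one_bin), 1000)
  expect_equal(spectral_centroid(one_bin), 1000)
  expect_equal(spectral_rolloff(one_bin, 20), 1000)
  expect_equal(spectral_rolloff(one_bin, 99), 1000)

  two_bins <- list(freq = c(1000, 3000), power = c(1, 1))
  expect_equal(mean_frequency(two_bins), 2000)
  expect_equal(median_frequency(two_bins), 1000)  # first bin reaching 50%
  expect_equal(spectral_centroid(two_bins), 2000)

  flat <- list(freq = seq(100, 1000, by = 100), power = rep(2, 10))
  expect_equal(mean_frequency(flat), mean(flat$freq))
  expect_equal(spectral_rolloff(flat, 95), flat$freq[10])
  expect_equal(spectral_rolloff(flat, 100), 1000)
})

test_that("spectral operations agree with loop oracles on random spectra", {
  local_seed(31, for (i in 1:100) {
    sp <- list(freq = sort(runif(16, 0, 8000)), power = runif(16))
    expect_equal(spectral_centroid(sp), oracle_centroid(sp$freq, sp$power),
                 tolerance = 1e-12)
    expect_equal(mean_frequency(sp), oracle_mean_freq(sp$freq, sp$power),
                 tolerance = 1e-12)
    expect_equal(median_frequency(sp), oracle_median_freq(sp$freq, sp$power))
    k <- runif(1, 5, 100)
    expect_equal(spectral_rolloff(sp, k), oracle_rolloff(sp$freq, sp$power, k))
  })
})

test_that("cepstra: silent frame collapses to the DCT of a constant", {
  cfg <- feature_config()
  cc <- mfcc14(numeric(160), 16000, cfg)
  # orthonormal DCT of the constant log-floor vector: c0 = sqrt(B) * log(eps)
  expect_equal(cc[1], sqrt(cfg$n_bands) * log(cfg$log_floor),
               tolerance = 1e-8, ignore_attr = TRUE)
  # higher coefficients of a constant log-energy vector vanish
  expect_equal(cc[-1], rep(0, 13), tolerance = 1e-10)
  gg <- gtcc14(numeric(160), 16000, cfg)
  expect_equal(gg[-1], rep(0, 13), tolerance = 1e-10)
})

test_that("cepstra: gain shifts only coefficient 0; tilt orders coef 1", {
  fr <- voiced_signal(seconds = 0.01)$samples[1:160]
  c1 <- mfcc14(fr, 16000)
  c2 <- mfcc14(4 * fr, 16000)
  expect_equal(c2[-1], c1[-1], tolerance = 1e-8)
  expect_gt(c2[1], c1[1])
  g1 <- gtcc14(fr, 16000); g2 <- gtcc14(4 * fr, 16000)
  expect_equal(g2[-1], g1[-1], tolerance = 1e-8)

  # opposite spectral tilt flips the sign ordering of coefficient 1
  t <- (0:159) / 16000
  dark <- rowSums(sapply(c(200, 400), function(f) sin(2 * pi * f * t)))
  bright <- rowSums(sapply(c(3000, 6000), function(f) sin(2 * pi * f * t)))
  expect_gt(mfcc14(dark, 16000)[2], mfcc14(bright, 16000)[2])
})

test_that("pitch and HNR behave on sine, noise and silence", {
  rate <- 16000
  t <- (0:639) / rate
  ph <- pitch_hnr(sin(2 * pi * 200 * t), rate)
  expect_lt(abs(1 / ph$pitch - 1 / 200) * rate, 1.5)  # within a lag quantum
  expect_gt(ph$hnr, 20)

  noise <- local_seed(9, rnorm(640))
  phn <- pitch_hnr(noise, rate)
  expect_true(is.na(phn$pitch))
  expect_lt(phn$hnr, 3)

  sil <- pitch_hnr(numeric(640), rate)
  expect_true(is.na(sil$pitch) && is.na(sil$hnr))
})

test_that("session summaries have 108 named entries in canonical order", {
  fm <- matrix(c(1, 2, 3), 3, 36)
  colnames(fm) <- feature_names_base()
  v <- summarize_features(fm)
  expect_length(v, 108)
  expect_identical(names(v), feature_names_summary())
  expect_equal(unname(v["mean_pitch"]), 2)
  expect_equal(unname(v["median_pitch"]), 2)
  expect_equal(unname(v["sd_pitch"]), 1)  # sample SD

  # identical frames: SD zero everywhere, mean = median = the value
  fm2 <- matrix(5, 4, 36); colnames(fm2) <- feature_names_base()
  v2 <- summarize_features(fm2)
  expect_true(all(v2[grep("^sd_", names(v2))] == 0))
  expect_true(all(v2[grep("^mean_", names(v2))] == 5))

  # a feature undefined everywhere raises a named error
  fm3 <- fm; fm3[, "pitch"] <- NA_real_
  expect_error(summarize_features(fm3), "pitch")
})

test_that("batch extractor agrees with the per-frame reference functions", {
  sig <- preprocess_audio(voiced_signal(seconds = 0.5))$signal
  cfg <- feature_config()
  fm <- extract_frame_features(sig, cfg)
  frames <- frame_signal(sig, cfg$frame_ms)
  expect_equal(nrow(fm), ncol(frames))
  for (j in local_seed(10, sample(ncol(frames), 8))) {
    fr <- frames[, j]
    expect_equal(fm[j, "zcr"], zcr(fr), ignore_attr = TRUE)
    en <- signal_energy(fr, cfg$energy_eps)
    expect_equal(fm[j, "energy"], en, ignore_attr = TRUE)
    sp <- spectrum_of(fr, sig$rate)
    expect_equal(fm[j, "centroid"], spectral_centroid(sp),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(fm[j, "median_freq"], median_frequency(sp),
                 ignore_attr = TRUE)
    expect_equal(fm[j, "rolloff"], spectral_rolloff(sp, cfg$rolloff_pct),
                 ignore_attr = TRUE)
    expect_equal(fm[j, paste0("mfcc_", 1:14)], mfcc14(fr, sig$rate, cfg),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(fm[j, paste0("gtcc_", 1:14)], gtcc14(fr, sig$rate, cfg),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("features are invariant to raw input scale after normalization", {
  sig <- voiced_signal(seconds = 0.4)
  v1 <- extract_features(sig)
  v2 <- extract_features(audio_signal(sig$samples * 0.2, sig$rate))
  expect_equal(v1, v2, tolerance = 1e-6)
  expect_length(v1, 108)
})
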