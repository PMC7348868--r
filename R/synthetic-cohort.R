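#' Specification of a synthetic two-class speech cohort
#'
#' Defines the study conditions a generated cohort emulates: two patient
#' classes (depression, dementia) whose voices differ only in the
#' spectral-envelope parameters of a source-filter model (spectral tilt and
#' first-formant position), while pitch and energy distributions are shared;
#' clinical scores weakly correlated with the envelope latent (negative
#' loading for HAMD17, positive for MMSE); demographics matching the
#' age-matched clinical cohort (depression 67.8 +/- 7.1 y, 83.3% female;
#' dementia 77.0 +/- 7.5 y, 72.4% female; ages clamped to 57-84).
#'
#' @param n_depression,n_dementia sessions per class.
#' @param session_seconds recording length per session (default 30 s for
#'   desk-scale runs; the emulated clinical sessions are >= 600 s).
#' @param sample_rate sampling rate, Hz.
#' @param class_separation between-class shift of each envelope latent, in
#'   within-class SD units (0 = classes identical).
#' @param score_loading target |Pearson r| between the envelope latent and
#'   the clinical scores (HAMD gets `-score_loading`, MMSE
#'   `+score_loading`).
#' @param score_noise_sd score-unit scale of the clinical scores around
#'   their centre (HAMD around 19, MMSE around 15).
#' @param sessions_per_subject sessions sharing one subject's voice
#'   parameters (with small per-session jitter).
#' @param age_params per-class list of `mean`, `sd`, `min`, `max` ages in
#'   years.
#' @param female_pct per-class probability of female sex.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   corpus.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_depression, n_dementia, session_seconds = 30,
                        sample_rate = 16000, class_separation = 3,
                        score_loading = 0.3, score_noise_sd = 5,
                        sessions_per_subject = 1L,
                        age_params = list(
                          depression = list(mean = 67.8, sd = 7.1,
                                            min = 57, max = 84),
                          dementia = list(mean = 77.0, sd = 7.5,
                                          min = 57, max = 84)),
                        female_pct = c(depression = 0.833,
                                       dementia = 0.724),
                        seed = 1L) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (session_seconds <= 0) stop("session_seconds must be positive")
  if (n_depression < 0 || n_dementia < 0) stop("counts must be nonnegative")
  if (sessions_per_subject < 1L) stop("sessions_per_subject must be >= 1")
  structure(list(n_depression = as.integer(n_depression),
                 n_dementia = as.integer(n_dementia),
                 session_seconds = session_seconds,
                 sample_rate = sample_rate,
                 class_separation = class_separation,
                 score_loading = score_loading,
                 score_noise_sd = score_noise_sd,
                 sessions_per_subject = as.integer(sessions_per_subject),
                 age_params = age_params, female_pct = female_pct,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# run code with a locally seeded RNG, restoring the caller's state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort manifest
#'
#' Draws per-subject voice parameters (f0 uniform on 100-250 Hz shared
#' across classes; spectral-tilt and first-formant latents shifted between
#' classes by `class_separation` within-class SDs), demographics, and
#' clinical scores as linear functions of the combined class-shifted
#' envelope latent `(z_tilt + z_form)/sqrt(2)` plus noise (HAMD17 with
#' negative loading, MMSE with positive loading), so that
#' envelope-tracking summary features such as the spectral centroid
#' realise the configured weak feature-score correlation. Audio is
#' synthesised lazily and deterministically per session via
#' [session_audio()] from the per-session `audio_seed` column.
#'
#' @param spec a [cohort_spec()].
#' @param with_audio also synthesise and attach the waveforms (list column
#'   of [audio_signal()]); off by default to keep memory flat.
#' @return list of class `speech_cohort` with `manifest` (one row per
#'   session) and, if requested, `audio`.
#' @export
generate_cohort <- function(spec, with_audio = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_subj <- c(depression = ceiling(spec$n_depression /
                                     spec$sessions_per_subject),
              dementia = ceiling(spec$n_dementia / spec$sessions_per_subject))
  manifest <- .with_seed(spec$seed, {
    rows <- list()
    sid <- 0L
    for (grp in c("depression", "dementia")) {
      n_sessions <- if (grp == "depression") spec$n_depression
                    else spec$n_dementia
      if (n_sessions == 0L) next
      off <- if (grp == "depression") +spec$class_separation / 2
             else -spec$class_separation / 2
      ap <- spec$age_params[[grp]]
      made <- 0L
      for (s in seq_len(n_subj[[grp]])) {
        sid <- sid + 1L
        f0 <- stats::runif(1, 100, 250)
        z_tilt <- off + stats::rnorm(1)
        z_form <- off + stats::rnorm(1)
        age <- round(.clamp(stats::rnorm(1, ap$mean, ap$sd), ap$min, ap$max))
        sex <- if (stats::runif(1) < spec$female_pct[[grp]]) "F" else "M"
        k <- min(spec$sessions_per_subject, n_sessions - made)
        for (r in seq_len(k)) {
          made <- made + 1L
          # session-level jitter around the subject's voice
          zt <- z_tilt + if (r > 1L) stats::rnorm(1, 0, 0.2) else 0
          zf <- z_form + if (r > 1L) stats::rnorm(1, 0, 0.2) else 0
          f0s <- f0 * stats::runif(1, 0.97, 1.03)
          # scores load on the combined envelope latent (tilt + formant),
          # the quantity the acoustic features respond to
          env <- (zt + zf) / sqrt(2)
          latent <- spec$score_loading * env +
            sqrt(1 - spec$score_loading^2) * stats::rnorm(1)
          hamd <- round(.clamp(19 - spec$score_noise_sd * latent, 8, 30))
          mmse_dem <- round(.clamp(15 + 0.8 * spec$score_noise_sd * latent,
                                   2, 23))
          rows[[length(rows) + 1L]] <- data.frame(
            session_id = sprintf("S%04d", length(rows) + 1L),
            subject_id = sprintf("subj%03d", sid),
            group = grp,
            age = age, sex = sex,
            hamd17 = if (grp == "depression") hamd else NA_integer_,
            mmse = if (grp == "dementia") mmse_dem
                   else sample(24:30, 1L),
            gds = if (grp == "dementia") sample(0:5, 1L)
                  else sample(6:15, 1L),
            duration = spec$session_seconds,
            sample_rate = spec$sample_rate,
            f0 = f0s, z_tilt = zt, z_form = zf,
            snr_db = stats::runif(1, 20, 28),
            peak = stats::runif(1, 0.1, 0.9),
            audio_seed = sample.int(.Machine$integer.max, 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  rownames(manifest) <- NULL
  out <- list(manifest = manifest, spec = spec)
  if (with_audio)
    out$audio <- lapply(seq_len(nrow(manifest)),
                        function(i) session_audio(manifest[i, ]))
  class(out) <- "speech_cohort"
  out
}

#' Synthesise the waveform of one manifest session
#'
#' Source-filter synthesis: a glottal pulse train at the session's f0 is
#' passed through a one-pole spectral-tilt filter and two formant
#' resonators, then mixed with white noise at the session's SNR and scaled
#' to the session's peak amplitude. The tilt pole and first formant are
#' monotone functions of the class-shifted latents `z_tilt`, `z_form`
#' (higher tilt latent = brighter spectrum), so class differences live in
#' the spectral envelope while pitch and energy overlap across classes.
#'
#' @param row one row of a [generate_cohort()] manifest.
#' @return an [audio_signal()].
#' @export
session_audio <- function(row) {
  stopifnot(nrow(row) == 1L)
  rate <- row$sample_rate
  len <- round(row$duration * rate)
  .with_seed(row$audio_seed, {
    period <- max(2L, round(rate / row$f0))
    x <- numeric(len)
    x[seq(1L, len, by = period)] <- 1
    a_tilt <- .clamp(0.7 - 0.08 * row$z_tilt, 0.3, 0.95)
    f1 <- .clamp(500 + 60 * row$z_form, 250, 950)
    f2 <- 1500 + stats::rnorm(1, 0, 60)
    y <- stats::filter(x, a_tilt, method = "recursive")
    y <- .resonator(y, f1, 80, rate)
    y <- .resonator(y, f2, 120, rate)
    # DC-blocking high-pass, as a real recording chain applies: keeps the
    # frame-mean (and hence sigma/mu energy) decoupled from the envelope
    y <- as.numeric(stats::filter(c(y[1], diff(as.numeric(y))), 0.995,
                                  method = "recursive"))
    rms_v <- sqrt(mean(y^2))
    noise_sd <- rms_v / 10^(row$snr_db / 20)
    y <- y + stats::rnorm(len, 0, noise_sd)
    audio_signal(y * (row$peak / max(abs(y))), rate)
  })
}

# second-order all-pole resonance at centre frequency f (Hz), bandwidth bw
.resonator <- function(x, f, bw, rate) {
  r <- exp(-pi * bw / rate)
  stats::filter(x, c(2 * r * cos(2 * pi * f / rate), -r^2),
                method = "recursive")
}

#' Write a cohort manifest to CSV
#'
#' One row per session with all session-record fields (and the synthesis
#' parameters, which are part of the reproducible record).
#'
#' @param cohort a `speech_cohort` from [generate_cohort()], or a manifest
#'   data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  manifest <- if (inherits(cohort, "speech_cohort")) cohort$manifest
              else cohort
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("empty cohort: nothing to write")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest from CSV
#' @param path CSV written by [write_manifest()].
#' @return manifest data frame.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write all session waveforms of a cohort as WAV files
#'
#' @param cohort a `speech_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest with an `audio_path` column added, invisibly.
#' @export
write_cohort_wavs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "speech_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- cohort$manifest
  m$audio_path <- file.path(dir, paste0(m$session_id, ".wav"))
  for (i in seq_len(nrow(m))) {
    sig <- session_audio(m[i, ])
    write_wav(sig$samples, m$audio_path[i], rate = sig$rate)
  }
  invisible(m)
}

#' Run preprocessing and feature extraction over a whole cohort
#'
#' Streams session by session (synthesise, preprocess, extract 108
#' features, discard audio) so memory stays flat for large cohorts.
#'
#' @param cohort a `speech_cohort` from [generate_cohort()].
#' @param config a [feature_config()].
#' @param preprocess run [preprocess_audio()] per session (default TRUE).
#' @param verbose print progress every 25 sessions.
#' @return data frame: `session_id`, `group`, then the 108 feature columns.
#' @export
cohort_features <- function(cohort, config = feature_config(),
                            preprocess = TRUE, verbose = FALSE) {
  m <- cohort$manifest
  feats <- matrix(NA_real_, nrow(m), 108L)
  for (i in seq_len(nrow(m))) {
    sig <- session_audio(m[i, ])
    v <- extract_features(sig, config, preprocess = preprocess)
    if (i == 1L) colnames(feats) <- names(v)
    feats[i, ] <- v
    if (verbose && i %% 25L == 0L)
      message("  extracted ", i, "/", nrow(m), " sessions")
  }
  cbind(data.frame(session_id = m$session_id, group = m$group,
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}
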