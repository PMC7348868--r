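# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, expr, envir = .fixtures)
  .fixtures[[name]]
}

# Small fully-processed cohort: 15 + 15 sessions of 5 s, separated classes.
tiny_cohort <- function() {
  fixture("tiny_cohort", {
    spec <- cohort_spec(15, 15, session_seconds = 5, class_separation = 3,
                        seed = 11)
    co <- generate_cohort(spec)
    list(spec = spec, cohort = co, features = cohort_features(co))
  })
}

# Study-scale cohorts used by the acceptance checks: 90 + 90 sessions of
# 30 s, at zero separation (null calibration) and at the default large
# separation (signal recovery).
study_cohort <- function(kind = c("null", "signal")) {
  kind <- match.arg(kind)
  fixture(paste0("study_", kind), {
    spec <- cohort_spec(90, 90, session_seconds = 30,
                        class_separation = if (kind == "null") 0 else 3,
                        seed = if (kind == "null") 101 else 202)
    co <- generate_cohort(spec)
    list(spec = spec, cohort = co, features = cohort_features(co))
  })
}

# A deterministic voiced test signal: pulse train through a resonator.
voiced_signal <- function(seconds = 1, f0 = 150, rate = 16000, seed = 4) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- round(seconds * rate)
  x <- numeric(n)
  x[seq(1, n, by = round(rate / f0))] <- 1
  r <- 0.98
  y <- stats::filter(x, c(2 * r * cos(2 * pi * 500 / rate), -r^2),
                     method = "recursive")
  y <- as.numeric(y) + rnorm(n, 0, 0.01)
  audio_signal(y / max(abs(y)) * 0.8, rate)
}
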