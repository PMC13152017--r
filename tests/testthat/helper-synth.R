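# Shared fixtures, all generated in code. The expensive cohorts used by the
# acceptance suite are built once per test run and cached here; videos are
# held at 60 s (the short end of the emulated 60-120 s range) to keep the
# suite inside its time budget — the statistics tested do not depend on
# duration beyond sampling noise.

.kin_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .kin_cache)) assign(key, force(expr), .kin_cache)
  get(key, .kin_cache)
}

# a short clean subject for structural tests
tiny_norm <- function(seed = 7, fps = 30, duration_s = 20) {
  s <- generate_subject(synth_class_params(1)$FM_plus, fps = fps,
                        duration_s = duration_s, seed = seed,
                        noise = quiet_noise())
  head_up_normalize(preprocess_pipeline(s$raw))
}

quiet_noise <- function(jitter = 0) {
  list(jitter_sd_px = jitter, dropout_prob = 0, spike_prob = 0,
       spike_magnitude_px = 0, extra_detection_prob = 0)
}

# 900-subject separable cohort: reused by the separability, scaling and
# parameter-recovery acceptance tests
big_effect_features <- function() {
  cached("big_effect", {
    co <- generate_cohort(synth_config(n_subjects = 900, effect_size = 1,
                                       seed = 424241,
                                       duration_range_s = c(60, 60)))
    list(features = cohort_feature_table(co), truth = co$truth)
  })
}

null_features_400 <- function() {
  cached("null400", {
    co <- generate_cohort(synth_config(n_subjects = 400, effect_size = 0,
                                       seed = 424242,
                                       duration_range_s = c(60, 60)))
    cohort_feature_table(co)
  })
}

# small random raw detections for I/O round trips
random_raw <- function(n = 100, seed = 1, extra = TRUE) {
  set.seed(seed)
  x <- matrix(runif(n * 17, 0, 1280), n, 17)
  y <- matrix(runif(n * 17, 0, 720), n, 17)
  conf <- matrix(runif(n * 17), n, 17)
  score <- runif(n)
  ex <- list()
  if (extra) {
    for (i in sample(n, 5)) {
      ex[[length(ex) + 1L]] <- list(frame = i - 1L, x = runif(17, 0, 1280),
                                    y = runif(17, 0, 720), conf = runif(17),
                                    score = runif(1))
    }
  }
  raw_detections(x, y, conf, score, ex, fps = 30, resolution = c(1280L, 720L),
                 subject_id = "R1")
}

# separable Gaussian feature table (fast stand-in for classifier unit tests)
gaussian_features <- function(n = 200, prevalence = 0.12, delta = 2,
                              seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, prevalence)
  X <- matrix(rnorm(n * 38), n, 38)
  X[y == 1, 1:6] <- X[y == 1, 1:6] + delta
  colnames(X) <- feature_names()
  list(X = X, y = y)
}
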