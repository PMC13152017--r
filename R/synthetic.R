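#' @title Synthetic infant keypoint cohorts
#' @description Generates labeled, infant-like COCO-17 keypoint cohorts
#'   with the statistical structure the pipeline assumes, so every stage is
#'   testable without clinical data: supine top-down geometry, limb
#'   endpoints driven by band-limited (0.5-4 Hz) sums of sinusoids gated by
#'   rest bouts, class differences encoded in amplitude, complexity
#'   (number of oscillatory components) and bilateral coupling, per-keypoint
#'   confidence with sub-0.8 dropout events, single-frame spike outliers,
#'   occasional spurious second detections, and mixed 15/30/120 FPS. Labels
#'   and the true generating parameters are always returned, so tests can
#'   check parameter recovery rather than eyeballing. No claim of
#'   biomechanical or clinical realism is made.
#' @name synthetic
NULL

#' Class-conditional movement parameter regimes
#'
#' The FM- (risk) regime differs from FM+ along the three axes the feature
#' set is designed to measure: smaller movement amplitude (with less
#' between-subject spread), fewer oscillatory components (lower
#' complexity/entropy), and stronger left-right coupling (more stereotyped,
#' mirror-like movement), plus longer rest bouts. `effect_size` scales the
#' FM+ to FM- parameter difference: 0 makes the classes identical (null
#' cohort), 1 is the full stated difference (a strongly separable cohort).
#'
#' @param effect_size class effect multiplier in \[0, 1\] (default 1).
#' @return list with `FM_plus` and `FM_minus` parameter lists
#'   (`amplitude_px`, `amplitude_sd_px`, `k_components` range, `coupling`,
#'   `rest_frac`, `freq_range_hz`).
#' @export
synth_class_params <- function(effect_size = 1) {
  assert_that(effect_size >= 0 && effect_size <= 1,
              "effect_size must be in [0, 1]")
  base <- list(amplitude_px = 45, amplitude_sd_px = 14,
               k_components = c(4L, 6L), coupling = 0.2, rest_frac = 0.15,
               freq_range_hz = c(0.5, 4))
  target <- list(amplitude_px = 18, amplitude_sd_px = 5,
                 k_components = c(1L, 2L), coupling = 0.85, rest_frac = 0.4,
                 freq_range_hz = c(0.5, 4))
  mix <- function(a, b) a + effect_size * (b - a)
  minus <- list(
    amplitude_px = mix(base$amplitude_px, target$amplitude_px),
    amplitude_sd_px = mix(base$amplitude_sd_px, target$amplitude_sd_px),
    k_components = round(mix(base$k_components, target$k_components)),
    coupling = mix(base$coupling, target$coupling),
    rest_frac = mix(base$rest_frac, target$rest_frac),
    freq_range_hz = base$freq_range_hz)
  list(FM_plus = base, FM_minus = minus)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the acquisition regime of a single-site clinical GMA
#' video collection: 10-12% FM- prevalence, 60-120 s recordings, 1280x720
#' resolution, frame rates overwhelmingly 30 FPS with rare 15 and 120 FPS
#' videos, >90% retention at the 0.8 confidence threshold.
#'
#' @param n_subjects cohort size.
#' @param prevalence FM- prevalence (default 0.11).
#' @param effect_size class effect multiplier passed to
#'   [synth_class_params()].
#' @param fps_options,fps_weights candidate frame rates and their sampling
#'   weights (defaults 15/30/120 weighted 3:1043:7).
#' @param duration_range_s video duration range in seconds (default 60-120).
#' @param resolution `c(width, height)` pixels.
#' @param jitter_sd_px per-frame keypoint jitter SD (default 1.5 px).
#' @param dropout_prob per-(frame, keypoint) probability of a
#'   low-confidence dropout event (default 0.05).
#' @param spike_prob per-(frame, keypoint) probability of a single-frame
#'   spike outlier (default 0.01).
#' @param spike_magnitude_px spike displacement (default 120 px).
#' @param extra_detection_prob per-frame probability of a spurious
#'   low-score second detection (default 0.02).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return list of class `kin_synth_config`.
#' @export
synth_config <- function(n_subjects = 100L, prevalence = 0.11,
                         effect_size = 1,
                         fps_options = c(15, 30, 120),
                         fps_weights = c(3, 1043, 7),
                         duration_range_s = c(60, 120),
                         resolution = c(1280L, 720L),
                         jitter_sd_px = 1.5,
                         dropout_prob = 0.05,
                         spike_prob = 0.01,
                         spike_magnitude_px = 120,
                         extra_detection_prob = 0.02,
                         seed = 1L) {
  assert_that(prevalence > 0 || prevalence == 0, "prevalence must be >= 0")
  assert_that(prevalence < 1 || prevalence == 1, "prevalence must be <= 1")
  assert_that(all(c(dropout_prob, spike_prob, extra_detection_prob) >= 0) &&
              all(c(dropout_prob, spike_prob, extra_detection_prob) <= 1),
              "probabilities must lie in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), prevalence = prevalence,
    effect_size = effect_size, fps_options = fps_options,
    fps_weights = fps_weights / sum(fps_weights),
    duration_range_s = duration_range_s, resolution = as.integer(resolution),
    jitter_sd_px = jitter_sd_px, dropout_prob = dropout_prob,
    spike_prob = spike_prob, spike_magnitude_px = spike_magnitude_px,
    extra_detection_prob = extra_detection_prob, seed = as.integer(seed)
  ), class = "kin_synth_config")
}

# band-limited oscillatory signal: sum of K random sinusoids, unit-RMS
oscillation <- function(tt, k, freq_range) {
  f <- stats::runif(k, freq_range[1], freq_range[2])
  ph <- stats::runif(k, 0, 2 * pi)
  a <- stats::runif(k, 0.5, 1)
  sig <- rowSums(vapply(seq_len(k), function(i) a[i] * sin(2 * pi * f[i] * tt + ph[i]),
                        numeric(length(tt))))
  sig / sqrt(sum(a^2) / 2)   # unit RMS regardless of K
}

# smooth on/off rest-bout envelope with approximately rest_frac time at rest
rest_envelope <- function(n, fps, rest_frac) {
  if (rest_frac <= 0) return(rep(1, n))
  env <- numeric(0)
  while (length(env) < n) {
    move_s <- stats::runif(1, 4, 10)
    rest_s <- stats::runif(1, 0.5, 1.5) * move_s * rest_frac / (1 - rest_frac)
    env <- c(env, rep(1, round(move_s * fps)), rep(0, round(rest_s * fps)))
  }
  env <- env[seq_len(n)]
  h <- max(1L, round(0.25 * fps))
  rolling_mean_vec(env, h)
}

#' Generate one synthetic subject recording
#'
#' Builds a supine base skeleton with plausible segment lengths, drives the
#' wrist/ankle endpoints with coupled + independent band-limited
#' oscillations gated by rest bouts, places elbows/knees between their
#' anchors with an outward bend (so joint angles covary with limb
#' extension), then corrupts the result with jitter, confidence dropouts,
#' single-frame spikes and occasional spurious second detections.
#'
#' @param params one class-parameter list from [synth_class_params()].
#' @param fps frame rate.
#' @param duration_s video duration in seconds.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param noise list of noise settings (defaults from [synth_config()]).
#' @param resolution `c(width, height)`.
#' @param subject_id subject identifier.
#' @return list with `raw` (a [raw_detections()]) and `truth` (the actual
#'   parameter draws: amplitude, k, coupling, rest_frac).
#' @export
generate_subject <- function(params, fps = 30, duration_s = 90, seed = 1L,
                             noise = NULL, resolution = c(1280L, 720L),
                             subject_id = "synth") {
  assert_that(fps > 0 && duration_s > 0 && round(duration_s * fps) >= 1,
              "generate_subject: fps and duration_s must be positive")
  noise <- noise %||% list(jitter_sd_px = 1.5, dropout_prob = 0.05,
                           spike_prob = 0.01, spike_magnitude_px = 120,
                           extra_detection_prob = 0.02)
  with_seed(seed, {
    n <- round(duration_s * fps)
    tt <- (seq_len(n) - 1L) / fps
    cx <- resolution[1] / 2; cy <- resolution[2] / 2
    torso <- stats::rnorm(1, 150, 10)
    assert_that(torso > 0, "infeasible geometry: non-positive torso length")

    amp <- max(0, stats::rnorm(1, params$amplitude_px, params$amplitude_sd_px))
    k <- if (params$k_components[1] >= params$k_components[2]) {
      params$k_components[1]
    } else sample(seq(params$k_components[1], params$k_components[2]), 1)
    cpl <- params$coupling
    env <- rest_envelope(n, fps, params$rest_frac)

    x <- matrix(0, n, 17); y <- matrix(0, n, 17)
    # static anchors (head up in image coordinates: smaller y = higher)
    put <- function(i, px, py) { x[, i] <<- px; y[, i] <<- py }
    put(1, cx, cy - 1.45 * torso)                    # nose
    put(2, cx - 0.08 * torso, cy - 1.5 * torso)      # eyes
    put(3, cx + 0.08 * torso, cy - 1.5 * torso)
    put(4, cx - 0.16 * torso, cy - 1.42 * torso)     # ears
    put(5, cx + 0.16 * torso, cy - 1.42 * torso)
    sway <- 2 * sin(2 * pi * 0.15 * tt + stats::runif(1, 0, 2 * pi))
    put(6, cx - 0.35 * torso + sway, cy - torso)     # shoulders
    put(7, cx + 0.35 * torso + sway, cy - torso)
    put(12, cx - 0.22 * torso + sway, cy)            # hips
    put(13, cx + 0.22 * torso + sway, cy)

    # movement bursts: Gaussian bumps on a small base level, mean-normalized.
    # Bilateral coordination is modelled at the event level: a burst is
    # shared by both sides with probability = coupling, otherwise one-sided.
    # This makes the coupling dial visible to a cross-correlation of
    # *speeds* (magnitudes barely reflect velocity-level mixing alone).
    bump_env <- function(centers) {
      e <- rep(0.15, n)
      for (ct in centers) e <- e + exp(-(tt - ct)^2 / (2 * 0.35^2))
      e / mean(e)
    }
    burst_rate <- 0.5  # bursts per second per limb pair
    pair_envelopes <- function() {
      n_sh <- stats::rpois(1, cpl * burst_rate * duration_s)
      n_l <- stats::rpois(1, (1 - cpl) * burst_rate * duration_s)
      n_r <- stats::rpois(1, (1 - cpl) * burst_rate * duration_s)
      shared <- stats::runif(n_sh, 0, duration_s)
      list(L = bump_env(c(shared, stats::runif(n_l, 0, duration_s))),
           R = bump_env(c(shared, stats::runif(n_r, 0, duration_s))))
    }
    limb_endpoint <- function(base_x, base_y, side_sign, mirror_x, mirror_y,
                              benv) {
      # mirrored shared carrier + independent carrier, RMS-preserving mix
      ind_x <- oscillation(tt, k, params$freq_range_hz)
      ind_y <- oscillation(tt, k, params$freq_range_hz)
      dx <- sqrt(cpl) * side_sign * mirror_x + sqrt(1 - cpl) * ind_x
      dy <- sqrt(cpl) * mirror_y + sqrt(1 - cpl) * ind_y
      list(x = base_x + amp * env * benv * dx,
           y = base_y + amp * env * benv * dy)
    }
    # shared carriers, one set for the arms and one for the legs
    arm_mx <- oscillation(tt, k, params$freq_range_hz)
    arm_my <- oscillation(tt, k, params$freq_range_hz)
    leg_mx <- oscillation(tt, k, params$freq_range_hz)
    leg_my <- oscillation(tt, k, params$freq_range_hz)
    arm_env <- pair_envelopes()
    leg_env <- pair_envelopes()

    lw <- limb_endpoint(cx - 0.78 * torso, cy - 0.75 * torso, -1,
                        arm_mx, arm_my, arm_env$L)
    rw <- limb_endpoint(cx + 0.78 * torso, cy - 0.75 * torso, +1,
                        arm_mx, arm_my, arm_env$R)
    la <- limb_endpoint(cx - 0.38 * torso, cy + 1.10 * torso, -1,
                        leg_mx, leg_my, leg_env$L)
    ra <- limb_endpoint(cx + 0.38 * torso, cy + 1.10 * torso, +1,
                        leg_mx, leg_my, leg_env$R)
    x[, 10] <- lw$x; y[, 10] <- lw$y
    x[, 11] <- rw$x; y[, 11] <- rw$y
    x[, 16] <- la$x; y[, 16] <- la$y
    x[, 17] <- ra$x; y[, 17] <- ra$y

    # mid-limb joints: between anchor and endpoint with an outward bend
    mid_joint <- function(ax, ay, ex, ey, out_sign, bend = 0.3) {
      mx <- ax + 0.55 * (ex - ax); my <- ay + 0.55 * (ey - ay)
      # perpendicular to the anchor->endpoint segment
      px <- -(ey - ay); py <- ex - ax
      nrm <- sqrt(px^2 + py^2); nrm[nrm < 1e-9] <- 1
      list(x = mx + out_sign * bend * torso * px / nrm,
           y = my + out_sign * bend * torso * py / nrm)
    }
    le <- mid_joint(x[, 6], y[, 6], x[, 10], y[, 10], -1)
    re <- mid_joint(x[, 7], y[, 7], x[, 11], y[, 11], +1)
    lk <- mid_joint(x[, 12], y[, 12], x[, 16], y[, 16], -1)
    rk <- mid_joint(x[, 13], y[, 13], x[, 17], y[, 17], +1)
    x[, 8] <- le$x; y[, 8] <- le$y;  x[, 9] <- re$x; y[, 9] <- re$y
    x[, 14] <- lk$x; y[, 14] <- lk$y; x[, 15] <- rk$x; y[, 15] <- rk$y

    # pose-estimator jitter on every keypoint
    x <- x + matrix(stats::rnorm(n * 17, 0, noise$jitter_sd_px), n, 17)
    y <- y + matrix(stats::rnorm(n * 17, 0, noise$jitter_sd_px), n, 17)

    conf <- matrix(pmin(1, pmax(0.82, stats::rnorm(n * 17, 0.95, 0.02))), n, 17)
    drop_mask <- matrix(stats::runif(n * 17) < noise$dropout_prob, n, 17)
    conf[drop_mask] <- stats::runif(sum(drop_mask), 0.2, 0.7)

    spike_mask <- matrix(stats::runif(n * 17) < noise$spike_prob, n, 17)
    nspk <- sum(spike_mask)
    if (nspk > 0) {
      x[spike_mask] <- x[spike_mask] +
        sample(c(-1, 1), nspk, replace = TRUE) * noise$spike_magnitude_px
      y[spike_mask] <- y[spike_mask] +
        sample(c(-1, 1), nspk, replace = TRUE) * noise$spike_magnitude_px
    }

    score <- pmin(1, pmax(0.5, stats::rnorm(n, 0.9, 0.02)))
    extra <- list()
    extra_frames <- which(stats::runif(n) < noise$extra_detection_prob)
    for (i in extra_frames) {
      extra[[length(extra) + 1L]] <- list(
        frame = i - 1L,
        x = x[i, ] + stats::rnorm(17, 0, 40),
        y = y[i, ] + stats::rnorm(17, 0, 40),
        conf = stats::runif(17, 0.1, 0.6),
        score = stats::runif(1, 0.1, 0.45))
    }

    raw <- raw_detections(x, y, conf, score, extra, fps = fps,
                          resolution = resolution, subject_id = subject_id)
    list(raw = raw,
         truth = list(amplitude_px = amp, k_components = k, coupling = cpl,
                      rest_frac = params$rest_frac, torso_px = torso,
                      fps = fps, duration_s = duration_s, seed = seed))
  })
}

#' Generate a labeled synthetic cohort
#'
#' Class assignment is Bernoulli(prevalence) for FM-; each subject's frame
#' rate, duration and movement parameters are drawn from a per-subject
#' child seed, so the cohort is bit-reproducible given the master seed.
#'
#' @param config a [synth_config()].
#' @return list of class `kin_synth_cohort` with `subjects` (list of
#'   `raw` + `truth` per subject), `cohort` (data.frame subject_id, label,
#'   sex), and `truth` (data.frame of the generating parameters).
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "kin_synth_config"))
  n <- config$n_subjects
  cls <- synth_class_params(config$effect_size)
  seeds <- child_seeds(config$seed, n + 1L)
  meta <- with_seed(seeds[n + 1L], {
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      label = ifelse(stats::runif(n) < config$prevalence, "FM_minus", "FM_plus"),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45)),
      fps = sample(config$fps_options, n, replace = TRUE,
                   prob = config$fps_weights),
      duration_s = stats::runif(n, config$duration_range_s[1],
                                config$duration_range_s[2]),
      stringsAsFactors = FALSE)
  })
  noise <- config[c("jitter_sd_px", "dropout_prob", "spike_prob",
                    "spike_magnitude_px", "extra_detection_prob")]
  subjects <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    par <- if (meta$label[i] == "FM_minus") cls$FM_minus else cls$FM_plus
    s <- generate_subject(par, fps = meta$fps[i],
                          duration_s = meta$duration_s[i], seed = seeds[i],
                          noise = noise, resolution = config$resolution,
                          subject_id = meta$subject_id[i])
    subjects[[i]] <- s
    truths[[i]] <- data.frame(subject_id = meta$subject_id[i],
                              label = meta$label[i],
                              amplitude_px = s$truth$amplitude_px,
                              k_components = s$truth$k_components,
                              coupling = s$truth$coupling,
                              rest_frac = s$truth$rest_frac,
                              fps = meta$fps[i],
                              duration_s = meta$duration_s[i],
                              stringsAsFactors = FALSE)
  }
  structure(list(subjects = subjects,
                 cohort = meta[, c("subject_id", "label", "sex")],
                 truth = do.call(rbind, truths),
                 config = config),
            class = "kin_synth_cohort")
}

#' @export
print.kin_synth_cohort <- function(x, ...) {
  cat(sprintf("kin_synth_cohort: %d subjects, %.1f%% FM-, seed %d\n",
              nrow(x$cohort), 100 * mean(x$cohort$label == "FM_minus"),
              x$config$seed))
  invisible(x)
}

#' Run the preprocessing + normalization + feature stages over a cohort
#'
#' Convenience composition used by tests, the pipeline runner and the
#' acceptance script: raw detections to the per-subject 38-feature table.
#'
#' @param cohort a `kin_synth_cohort`, or a list of [raw_detections()].
#' @param labels optional named labels (unneeded for a synthetic cohort).
#' @param preprocess a [preprocess_config()].
#' @param features_cfg a [features_config()].
#' @return feature table data.frame (`subject_id`, `label`, 38 features).
#' @export
cohort_feature_table <- function(cohort, labels = NULL,
                                 preprocess = preprocess_config(),
                                 features_cfg = features_config()) {
  raws <- if (inherits(cohort, "kin_synth_cohort")) {
    lapply(cohort$subjects, `[[`, "raw")
  } else cohort
  if (inherits(cohort, "kin_synth_cohort") && is.null(labels)) {
    labels <- stats::setNames(cohort$cohort$label, cohort$cohort$subject_id)
  }
  sk <- coco17_skeleton()
  norms <- lapply(raws, function(r) {
    head_up_normalize(preprocess_pipeline(r, preprocess), sk)
  })
  extract_feature_table(norms, labels = labels, skeleton = sk,
                        config = features_cfg)
}
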