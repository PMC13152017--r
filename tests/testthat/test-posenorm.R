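make_clean <- function(x, y, fps = 30, id = "t") {
  structure(list(x = x, y = y, fps = fps, subject_id = id,
                 retention = 1, mask_log = rep(0, 17)),
            class = "kin_clean")
}

# apply a global similarity transform (rotation theta, scale s, shift t)
similarity <- function(seq, theta, s, tx, ty) {
  xr <- s * (seq$x * cos(theta) - seq$y * sin(theta)) + tx
  yr <- s * (seq$x * sin(theta) + seq$y * cos(theta)) + ty
  seq$x <- xr; seq$y <- yr
  seq
}

test_that("head-up normalization fixes the torso frame", {
  nm <- tiny_norm(seed = 3)
  sk <- coco17_skeleton()
  sh <- sk$torso_anchors$shoulders; hp <- sk$torso_anchors$hips
  msx <- rowMeans(nm$x[, sh]); msy <- rowMeans(nm$y[, sh])
  mhx <- rowMeans(nm$x[, hp]); mhy <- rowMeans(nm$y[, hp])
  torso <- sqrt((msx - mhx)^2 + (msy - mhy)^2)
  expect_equal(median(torso), 1, tolerance = 1e-9)
  # mid-shoulder above mid-hip (smaller y) in at least 99% of frames
  expect_gte(mean(msy < mhy), 0.99)
})

test_that("normalization is invariant under global similarity transforms", {
  s <- generate_subject(synth_class_params(1)$FM_plus, fps = 30,
                        duration_s = 15, seed = 9, noise = quiet_noise())
  cl <- preprocess_pipeline(s$raw)
  base <- head_up_normalize(cl)
  for (par in list(c(pi / 2, 3, 50, -20), c(1.1, 0.4, -300, 700))) {
    tr <- head_up_normalize(similarity(cl, par[1], par[2], par[3], par[4]))
    expect_equal(tr$x, base$x, tolerance = 1e-6)
    expect_equal(tr$y, base$y, tolerance = 1e-6)
  }
})

test_that("degenerate torso raises an error", {
  x <- matrix(1, 50, 17); y <- matrix(2, 50, 17)
  expect_error(head_up_normalize(make_clean(x, y)), "degenerate torso")
})

test_that("wingspan ratio matches brute-force recomputation and symmetry", {
  nm <- tiny_norm(seed = 5)
  sk <- coco17_skeleton()
  body <- setdiff(1:17, sk$head_indices)
  oracle <- mean(vapply(seq_len(nrow(nm$x)), function(i) {
    (max(nm$x[i, body]) - min(nm$x[i, body])) /
      (max(nm$y[i, body]) - min(nm$y[i, body]))
  }, numeric(1)))
  expect_equal(wingspan_ratio(nm), oracle)

  # equal x/y extents -> exactly 1; 90 deg rotation -> reciprocal
  sq <- nm
  sq$x[] <- rep(seq(-1, 1, length.out = 17), each = nrow(nm$x))
  sq$y[] <- rep(seq(1, -1, length.out = 17), each = nrow(nm$x))
  expect_equal(wingspan_ratio(sq), 1.0)
  rot <- nm; rot$x <- -nm$y; rot$y <- nm$x
  expect_equal(wingspan_ratio(rot), mean(vapply(seq_len(nrow(nm$x)), function(i) {
    (max(nm$y[i, body]) - min(nm$y[i, body])) /
      (max(nm$x[i, body]) - min(nm$x[i, body]))
  }, numeric(1))))
})

test_that("synthetic supine cohort wingspan ratio sits in the expected band", {
  co <- generate_cohort(synth_config(n_subjects = 25, seed = 808,
                                     duration_range_s = c(30, 30)))
  ws <- vapply(co$subjects, function(s) {
    wingspan_ratio(head_up_normalize(preprocess_pipeline(s$raw)))
  }, numeric(1))
  expect_gte(mean(ws), 0.77 - 0.12)
  expect_lte(mean(ws), 0.77 + 0.12)
})

test_that("two-sample KS statistic matches an ECDF sweep and stats::ks.test", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 101:105)$statistic, 1)
  set.seed(31)
  for (i in 1:5) {
    # large samples so the reference test is asymptotic too; our p-value
    # carries the small-sample lambda correction, hence the loose tolerance
    a <- rnorm(150); b <- rnorm(200, mean = 0.2)
    res <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_lt(abs(res$p.value - ref$p.value), 0.02)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("retention report flags exactly the low-retention videos", {
  mk <- function(id, r) {
    structure(list(subject_id = id, retention = r), class = "kin_clean")
  }
  set.seed(17)
  rets <- runif(20, 0.7, 1)
  rep_ <- retention_report(lapply(seq_along(rets),
                                  function(i) mk(paste0("s", i), rets[i])))
  expect_equal(sum(rep_$flagged), sum(rets < 0.9))
  expect_equal(attr(rep_, "cohort_mean"), mean(rets))
  clean <- retention_report(list(mk("a", 1), mk("b", 1)))
  expect_false(any(clean$flagged))
})
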