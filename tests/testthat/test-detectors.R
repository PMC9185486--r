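smooth_coord <- function(n = 2000, seed = 41, noise = 0.3) {
  set.seed(seed)
  t <- seq_len(n) / 100
  15 * sin(2 * pi * 0.2 * t + 1) + 8 * sin(2 * pi * 0.45 * t) +
    rnorm(n, 0, noise)
}

test_that("peak detection flags an isolated spike exactly and nothing on clean signal", {
  x <- smooth_coord()
  expect_equal(sum(detect_peaks(x)), 0)
  x1 <- x
  x1[1000] <- x1[1000] + 15
  expect_equal(which(detect_peaks(x1)), 1000)
  # sequences shorter than the windows yield an empty mask
  expect_equal(detect_peaks(x[1:10]), rep(FALSE, 10))
})

test_that("two spikes a few samples apart fail the isolation screen", {
  x <- smooth_coord(seed = 42)
  x[1000] <- x[1000] + 15
  x[1003] <- x[1003] - 12
  expect_equal(sum(detect_peaks(x)), 0)
})

test_that("heavy-noise bursts are recovered with high overlap, short bursts rejected", {
  x <- smooth_coord(seed = 43)
  expect_equal(sum(detect_heavy_noise(x)), 0)
  set.seed(44)
  x2 <- x
  x2[200:300] <- x2[200:300] + rnorm(101, 0, 10)
  m <- detect_heavy_noise(x2)
  truth <- rep(FALSE, length(x2))
  truth[200:300] <- TRUE
  iou <- sum(m & truth) / sum(m | truth)
  expect_gte(iou, 0.8)
  # a 10-frame burst is below the minimal segment length
  set.seed(45)
  x3 <- x
  x3[500:509] <- x3[500:509] + rnorm(10, 0, 10)
  expect_equal(sum(detect_heavy_noise(x3) & seq_along(x3) %in% 480:530), 0)
})

test_that("step changes are recovered within two frames, short steps left alone", {
  x <- smooth_coord(seed = 46)
  expect_equal(sum(detect_step_changes(x)), 0)
  x2 <- x
  x2[301:400] <- x2[301:400] + 10     # frames 300..399 (0-based), length 100
  m <- detect_step_changes(x2)
  expect_true(any(m))
  r <- range(which(m))
  expect_lte(abs(r[1] - 301), 2)
  expect_lte(abs(r[2] - 401), 2)
  # a 10-frame rectangle is below min_len for this stage
  x3 <- x
  x3[301:310] <- x3[301:310] + 10
  expect_equal(sum(detect_step_changes(x3)), 0)
})

test_that("slow-change hysteresis respects its thresholds and length gates", {
  p <- detector_params()
  expect_equal(sum(detect_slow_changes(rep(0, 1000), 1, p)), 0)
  set.seed(47)
  res <- rnorm(2000, 0, 0.5)
  sig <- 0.5
  tri <- 10 * (1 - abs(2 * seq(0, 1, length.out = 150) - 1))
  res[901:1050] <- res[901:1050] + tri
  m <- detect_slow_changes(res, sig, p)
  # detected interval covers at least the span where the smoothed
  # residual magnitude stays above the lower threshold
  sm <- savgol(res, p$slow$sg_L, p$slow$sg_M, "low")
  core <- which(abs(sm) > 3 * sig)
  core <- core[core >= 901 & core <= 1050]
  expect_true(all(m[core]))
  expect_gte(sum(m[901:1050]), 100)
  # a 30-frame hill is discarded as a predictor fluctuation
  res2 <- rnorm(2000, 0, 0.5)
  res2[901:930] <- res2[901:930] + 10 * (1 - abs(2 * seq(0, 1, length.out = 30) - 1))
  expect_equal(sum(detect_slow_changes(res2, sig, p)), 0)
  expect_error(detect_slow_changes(res, NA_real_, p), "sigma_R")
})

test_that("interval cleaning interpolates linearly and extends constants at edges", {
  x <- seq(0, 10, length.out = 101)
  mask <- rep(FALSE, 101)
  expect_identical(clean_intervals(x, mask), x)
  mask[40:60] <- TRUE
  expect_equal(clean_intervals(x + 0, mask), x)   # linear-in-time restored exactly
  mask2 <- rep(FALSE, 101)
  mask2[1:10] <- TRUE
  y <- clean_intervals(x, mask2)
  expect_equal(y[1:10], rep(x[11], 10))
  expect_error(clean_intervals(x, rep(TRUE, 101)), "fully-masked")
})

test_that("threshold scaling leaves detections invariant under coordinate rescaling", {
  x <- smooth_coord(seed = 48)
  x[1200] <- x[1200] + 12
  x[600:680] <- x[600:680] + 8
  for (k in c(0.1, 10)) {
    expect_identical(detect_peaks(x * k), detect_peaks(x))
    expect_identical(detect_step_changes(x * k), detect_step_changes(x))
    expect_identical(detect_heavy_noise(x * k), detect_heavy_noise(x))
  }
})

test_that("detector sensitivity grows with injected amplitude", {
  hits <- vapply(c(5, 10, 20), function(a) {
    x <- smooth_coord(seed = 49, noise = 1)
    x[701:800] <- x[701:800] + a
    sum(detect_step_changes(x))
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
  expect_gt(hits[3], 0)
})

test_that("the staged pipeline classifies a clean sequence as all clear", {
  gen <- generate_base_sequence(base_sequence_config(
    n_markers = 8, n_groups = 2, duration_s = 20, seed = 50))
  rep_ <- classify_sequence(gen$seq, gen$hier)
  expect_lt(mean(rep_$class_mask != 0), 0.01)
  expect_s3_class(rep_, "detection_report")
})

test_that("one injected distortion of each class is recovered with its own class", {
  gen <- generate_base_sequence(base_sequence_config(
    n_markers = 8, n_groups = 2, duration_s = 30, seed = 51))
  pos <- gen$seq$positions
  lab <- gen$seq$labels
  pos[, lab[1], 1] <- inject_distortion(pos[, lab[1], 1], "peak", 500, 1, 15)
  set.seed(52)
  pos[, lab[3], 2] <- inject_distortion(pos[, lab[3], 2], "heavy_noise",
                                        1000, 80, 10)
  pos[, lab[5], 3] <- inject_distortion(pos[, lab[5], 3], "step", 1600, 60, 10)
  pos[, lab[7], 1] <- inject_distortion(pos[, lab[7], 1], "slow", 2200, 150, 12)
  dirty <- mocap_sequence(pos, lab, 100)
  rep_ <- classify_sequence(dirty, gen$hier)
  expect_equal(unname(rep_$class_mask[501, lab[1], 1]), 1L)
  noise_span <- rep_$class_mask[1001:1080, lab[3], 2]
  expect_gt(mean(noise_span == 2L), 0.7)
  step_span <- rep_$class_mask[1601:1660, lab[5], 3]
  expect_gt(mean(step_span == 3L), 0.8)
  slow_span <- rep_$class_mask[2201:2350, lab[7], 1]
  expect_gt(mean(slow_span == 4L), 0.4)
  # intervals carry their class and exclusivity holds by construction
  expect_true(all(rep_$intervals$klass %in%
                    c("peak", "heavy_noise", "step", "slow")))
  # re-running gives an identical report (determinism contract)
  rep2 <- classify_sequence(dirty, gen$hier)
  expect_identical(rep_$class_mask, rep2$class_mask)
  expect_identical(rep_$intervals, rep2$intervals)
})

test_that("true gaps are bridged for processing and never classified", {
  gen <- generate_base_sequence(base_sequence_config(
    n_markers = 8, n_groups = 2, duration_s = 15, seed = 53))
  pos <- gen$seq$positions
  pos[301:340, 2, ] <- NA            # a 40-frame dropout on one marker
  gappy <- mocap_sequence(pos, gen$seq$labels, 100)
  expect_true(all(gappy$gap_mask[301:340, 2]))
  rep_ <- suppressWarnings(classify_sequence(gappy, gen$hier))
  expect_true(all(rep_$class_mask[301:340, 2, ] == 0L))
  # gap samples are excluded from scoring
  cm <- confusion(array(0L, dim = dim(rep_$class_mask)), rep_, seq = gappy)
  expect_equal(sum(cm), length(rep_$class_mask) - 3 * 40)
})
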