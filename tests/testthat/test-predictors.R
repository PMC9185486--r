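test_that("moving median matches the brute-force shrinking-window oracle", {
  expect_equal(moving_median(rep(3.5, 20), 5), rep(3.5, 20))
  expect_equal(moving_median(c(0, 0, 0, 10, 0, 0, 0), 5), rep(0, 7))
  expect_error(moving_median(1:10, 4), "odd")
  set.seed(11)
  for (w in c(3, 7, 19)) {
    x <- rnorm(200)
    expect_equal(moving_median(x, w), naive_moving_median(x, w))
  }
})

test_that("Savitzky-Golay reproduces low-order polynomials and splits exactly", {
  t <- seq(-1, 1, length.out = 120)
  x <- 2 - 3 * t + 0.5 * t^3 - t^5
  expect_equal(savgol(x, 5, 13, "low"), x, tolerance = 1e-10)
  expect_equal(savgol(x, 5, 13, "high"), rep(0, 120), tolerance = 1e-10)
  # defaults L = 5, M = 13 accepted
  expect_silent(savgol(rnorm(50), mode = "low"))
  expect_error(savgol(rnorm(50), 13, 13), "smaller")
  # x = low + high identically
  set.seed(12)
  x <- cumsum(rnorm(300))
  expect_equal(savgol(x, 5, 13, "low") + savgol(x, 5, 13, "high"), x)
})

test_that("Savitzky-Golay equals a per-window least-squares fit at interior points", {
  set.seed(13)
  x <- rnorm(100)
  low <- savgol(x, 5, 13, "low")
  for (i in c(7, 30, 50, 94))
    expect_equal(low[i], naive_savgol_mid(x, 5, 13, i), tolerance = 1e-9)
  # the filter stays stable at the high-order repair setting
  sm <- savgol(1000 + sin(seq_len(500) / 20), 13, 101, "low")
  expect_lt(max(abs(sm - (1000 + sin(seq_len(500) / 20)))), 0.01)
})

test_that("Laplace dispersion follows b = sigma/sqrt(2) and is recovered from draws", {
  expect_equal(fit_laplace(rep(0, 10))$b, 0)
  expect_equal(fit_laplace(rep(0, 10))$sigma_R, 0)
  x <- c(-1, 1) * sqrt(2) / sd(c(-1, 1))  # sample sd is exactly sqrt(2)
  expect_equal(fit_laplace(x)$b, 1)
  set.seed(14)
  u <- runif(1e5) - 0.5
  draws <- -sign(u) * log(1 - 2 * abs(u))  # Laplace(0, b = 1)
  est <- fit_laplace(draws)
  expect_lt(abs(est$b - 1), 0.02)
  expect_error(fit_laplace(rep(NA_real_, 5)), "finite")
})

test_that("loose polynomial fit matches the normal-equations oracle", {
  g <- make_group_seq(n = 400, seed = 21)
  mod <- fit_loose_polynomial(g$seq, g$hier, "A1", k = 1, L = 1)
  # oracle: beta = (X'X)^-1 X'Y assembled independently
  n <- 400
  regs <- mod$regressors
  X <- cbind(1, do.call(cbind, lapply(regs, function(r) {
    xyz <- marker_xyz(g$seq, r)
    cbind(xyz, rbind(matrix(NA, 1, 3), xyz[-n, ]))
  })))
  ok <- complete.cases(X)
  Y <- marker_xyz(g$seq, "A1")[ok, ]
  Xo <- X[ok, ]
  beta <- solve(crossprod(Xo), crossprod(Xo, Y))
  expect_equal(unname(mod$coef), unname(beta), tolerance = 1e-8)
})

test_that("an affine function of the parent is predicted with near-zero residual", {
  g <- make_group_seq(n = 500, seed = 22)
  pos <- g$seq$positions
  pos[, "A1", 1] <- 2 + 0.5 * pos[, "P1", 1]
  pos[, "A1", 2] <- -1 + 0.25 * pos[, "P1", 2]
  pos[, "A1", 3] <- 3 + pos[, "P1", 3]
  s <- mocap_sequence(pos, g$seq$labels, 100)
  h <- body_hierarchy(groups = list(parent = c("P1", "P2"), arm = c("A1", "A2")),
                      parents = list(arm = "parent"))
  hseq <- mocap_sequence(pos[, c("P1", "P2", "A1", "A2"), ],
                         c("P1", "P2", "A1", "A2"), 100)
  mod <- fit_loose_polynomial(hseq, h, "A1", k = 3, L = 4)
  expect_lt(mod$sigma_R, 1e-6)
})

test_that("the loose design has 1 + 3(k+1)ML columns and never the target's own values", {
  g <- make_group_seq(n = 300, seed = 23)
  mod <- fit_loose_polynomial(g$seq, g$hier, "A1", k = 3, L = 4)
  M <- length(mod$regressors)   # parent representative + 3 siblings
  expect_equal(M, 4)
  expect_equal(nrow(mod$coef), 1 + 3 * (3 + 1) * M * 4)
  expect_false(any(grepl("^A1_", rownames(mod$coef))))
})

test_that("loose FFNN respects its contract: shape, identity, reproducibility, defaults", {
  expect_equal(ffnn_params()$P, 5)
  g <- make_group_seq(n = 1200, seed = 24)
  p <- ffnn_params(max_epochs = 40, train_stride = 4)
  m1 <- suppressWarnings(fit_loose_ffnn(g$seq, g$hier, "A1", p))
  m2 <- suppressWarnings(fit_loose_ffnn(g$seq, g$hier, "A1", p))
  # bit-reproducible under a fixed seed
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict_positions(m1), predict_positions(m2))
  # residual + prediction reconstructs the observation exactly
  res <- predict_residual(m1, g$seq)
  pred <- predict_positions(m1, g$seq)
  obs <- marker_xyz(g$seq, "A1")
  ok <- !is.na(pred[, 1])
  expect_equal(pred[ok, ] + res[ok, ], obs[ok, ])
  # frames without full lag context are flagged, not fabricated
  expect_true(all(is.na(pred[1, ])))
  # zero-residual identity
  expect_equal(unname(obs - pred)[ok, ] - res[ok, ],
               matrix(0, sum(ok), 3), ignore_attr = TRUE)
})

test_that("averaging identical replicas returns the replica (final-step identity)", {
  g <- make_group_seq(n = 600, seed = 25)
  p <- ffnn_params(max_epochs = 30)
  mod <- suppressWarnings(fit_loose_ffnn(g$seq, g$hier, "A1", p))
  # force all P replicas to share the first replica's output weights
  w <- mod$weights
  for (r in 1:3) {
    cols <- seq(r, 3 * p$P, by = 3)
    w$W3[, cols] <- w$W3[, cols[1]]
    w$b3[cols] <- w$b3[cols[1]]
  }
  mod$weights <- w
  pred <- predict_positions(mod, g$seq)
  # recompute a single replica by hand
  X <- mocapclean:::loose_design(g$seq, mod$regressors, p$k, p$L)
  ma <- apply(marker_xyz(g$seq, "A1"), 2, mocapclean:::moving_average,
              window = p$ma_window)
  X <- cbind(X, ma)
  ok <- complete.cases(X)
  f <- mocapclean:::ffnn_forward(w, mocapclean:::std_apply(X[ok, ], mod$x_std))
  one <- sweep(sweep(f$Yh[, 1:3], 2, mod$y_std$scl, `*`), 2,
               mod$y_std$ctr, `+`)
  expect_equal(unname(pred[ok, ]), unname(one))
})

test_that("the loose FFNN stays loose: an injected step barely moves the prediction", {
  # at the operating scale (a 60 s quasi-static body) the prediction is
  # anchored to the neighbours and must not follow an artifact interval
  gen <- generate_base_sequence(base_sequence_config(seed = 26))
  m <- "M13_seg4"
  amp <- 12
  pos <- gen$seq$positions
  pos[, m, 1] <- inject_distortion(pos[, m, 1], "step", 3000, 90, amp)
  dirty <- mocap_sequence(pos, gen$seq$labels, 100)
  mod <- fit_loose_ffnn(dirty, gen$hier, m)
  expect_gt(amp, 5 * mod$sigma_R)
  expect_lte(90, mod$params$ma_window / 2 + 45)  # within the MA guard band
  pred_dirty <- predict_positions(mod, dirty)
  clean_mod <- fit_loose_ffnn(gen$seq, gen$hier, m)
  pred_clean <- predict_positions(clean_mod, gen$seq)
  span <- 3001:3090
  shift <- mean(pred_dirty[span, 1] - pred_clean[span, 1])
  expect_lt(abs(shift), 0.5 * amp)
  # and the deviation stands out in the residual
  res <- predict_residual(mod, dirty)
  expect_gt(mean(abs(res[span, 1])), 3 * mod$sigma_R)
  outside <- c(500:2500, 3500:5500)
  expect_lt(mean(abs(res[outside, 1])), 3 * mod$sigma_R)
})

test_that("FFNN residual exposes a slow hill sharply enough for hysteresis detection", {
  gen <- generate_base_sequence(base_sequence_config(seed = 27))
  m <- "M09_seg3"
  pos <- gen$seq$positions
  pos[, m, 2] <- inject_distortion(pos[, m, 2], "slow", 2900, 150, 10)
  dirty <- mocap_sequence(pos, gen$seq$labels, 100)
  fmod <- fit_loose_ffnn(dirty, gen$hier, m)
  fres <- predict_residual(fmod, dirty)
  span <- 2901:3050
  # the hill rises clearly above the FFNN residual dispersion ...
  expect_gt(max(abs(fres[span, 2])), 4 * fmod$sigma_R_coord[2])
  # ... and the hysteresis detector recovers an interval inside the hill
  msk <- detect_slow_changes(fres[, 2], fmod$sigma_R_coord[2])
  expect_gt(sum(msk[span]), 50)
  expect_equal(sum(msk[-(2850:3100)]), 0)
})
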