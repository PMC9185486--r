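# shared fixtures and independent oracles for the test suite

# small sequence with one rigid-ish group of `n_sib + 1` markers plus a
# parent group, correlated by construction
make_group_seq <- function(n = 2000, fps = 100, seed = 1,
                           noise_sd = 0.3) {
  set.seed(seed)
  t <- seq_len(n) / fps
  sway <- function(amp) {
    f <- runif(3, 0.05, 0.5); ph <- runif(3, 0, 2 * pi)
    s <- sin(2 * pi * f[1] * t + ph[1]) + sin(2 * pi * f[2] * t + ph[2]) +
      sin(2 * pi * f[3] * t + ph[3])
    amp * s / sd(s) / 3
  }
  base <- vapply(1:3, function(i) sway(30), numeric(n))
  mk <- function(off) base + matrix(rep(off, each = n), n) +
    matrix(rnorm(3 * n, 0, noise_sd), n)
  labels <- c("P1", "P2", "A1", "A2", "A3", "A4")
  pos <- array(NA_real_, c(n, 6, 3))
  offs <- list(c(0, 0, -200), c(50, 0, -200), c(0, 0, 0), c(100, 0, 0),
               c(0, 120, 0), c(60, 60, 40))
  for (i in 1:6) pos[, i, ] <- mk(offs[[i]])
  seq <- mocap_sequence(pos, labels, fps)
  hier <- body_hierarchy(
    groups = list(parent = c("P1", "P2"), arm = c("A1", "A2", "A3", "A4")),
    parents = list(arm = "parent"))
  list(seq = seq, hier = hier)
}

# brute-force windowed extreme with replicate padding (oracle for morph1d)
naive_extreme <- function(x, s, f) {
  h <- (s - 1) %/% 2
  n <- length(x)
  pad <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) f(pad[i:(i + 2 * h)]), numeric(1))
}

# brute-force moving median with symmetric shrinking windows
naive_moving_median <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    median(x[(i - hh):(i + hh)])
  }, numeric(1))
}

# direct per-window least-squares polynomial value at the window centre
naive_savgol_mid <- function(x, L, M, i) {
  h <- (M - 1) %/% 2
  win <- x[(i - h):(i + h)]
  fit <- lm(win ~ poly(seq(-h, h), L))
  unname(predict(fit)[h + 1])
}

# one-vs-rest rates straight from the counts (oracle for class_metrics)
naive_rates <- function(cm, i) {
  cm <- matrix(as.numeric(cm), nrow(cm))
  tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
  tn <- sum(cm[-i, -i])
  list(TPR = 100 * tp / (tp + fn), FNR = 100 * fn / (tp + fn),
       FPR = 100 * fp / (tp + fp), PPV = 100 * tp / (tp + fp),
       F = tp / (tp + (fp + fn) / 2),
       MCC = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# lazily-computed scaled-down synthetic classification experiment shared
# by the acceptance blocks (one 50-fold run feeds several checks)
e1_cache_env <- new.env(parent = emptyenv())
acceptance_e1 <- function() {
  if (is.null(e1_cache_env$res)) {
    e1_cache_env$res <- suppressWarnings(
      run_experiment_e1(folds = 50, share = 0.2, mu_amp = 10, seed = 2026,
                        baselines = TRUE))
  }
  e1_cache_env$res
}
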