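#' Per-sample class labels implied by a ground-truth log
#'
#' Expands a distortion-interval log into an integer `frames x markers
#' x 3` array of class codes (0 = clear, 1 = peak, 2 = heavy_noise,
#' 3 = step, 4 = slow), the same layout as a `detection_report`'s
#' `class_mask`.
#'
#' @param seq the [mocap_sequence] the log refers to.
#' @param truth data.frame with `marker`, `coord`, `start`, `end`,
#'   `klass` (0-based half-open intervals).
#' @return integer array of class codes.
#' @export
truth_class_mask <- function(seq, truth) {
  cls <- array(0L, dim = c(n_frames(seq), n_markers(seq), 3),
               dimnames = list(NULL, seq$labels, c("x", "y", "z")))
  for (i in seq_len(nrow(truth))) {
    tv <- truth[i, ]
    code <- match(tv$klass, distortion_classes) - 1L
    cls[(tv$start + 1L):tv$end, tv$marker, tv$coord + 1L] <- code
  }
  cls
}

#' Sample-level confusion matrix over the five classes
#'
#' Tallies marker-coordinate-frame samples; rows are the true class,
#' columns the predicted class, ordered clear, peak, heavy_noise, step,
#' slow.  Gap samples are excluded.
#'
#' @param truth integer array or vector of true class codes (0-4), or a
#'   data.frame log (converted with [truth_class_mask]).
#' @param pred a `detection_report` or an integer array/vector of
#'   predicted codes with the same shape as `truth`.
#' @param seq the sequence (required when `truth` is a data.frame, and
#'   for gap exclusion).
#' @return 5x5 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, pred, seq = NULL) {
  if (is.data.frame(truth)) {
    if (is.null(seq)) stop("`seq` is required for a data.frame truth log")
    truth <- truth_class_mask(seq, truth)
  }
  if (inherits(pred, "detection_report")) pred <- pred$class_mask
  if (!identical(dim(truth), dim(pred)) ||
      length(truth) != length(pred))
    stop("truth and prediction shapes differ")
  keep <- rep(TRUE, length(truth))
  if (!is.null(seq) && any(seq$gap_mask)) {
    gaps <- array(rep(seq$gap_mask, 3), dim = dim(truth))
    keep <- !as.vector(gaps)
  }
  tf <- factor(as.vector(truth)[keep], levels = 0:4,
               labels = distortion_classes)
  pf <- factor(as.vector(pred)[keep], levels = 0:4,
               labels = distortion_classes)
  cm <- table(truth = tf, predicted = pf)
  structure(unclass(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = truth, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest classification rates for a class
#'
#' Derives tp/fp/tn/fn for the given class from a confusion matrix and
#' returns the per-class rates: sensitivity `TPR = tp/(tp+fn)`,
#' miss rate `FNR = fn/(tp+fn)`, `FPR = fp/(tp+fp)` (the fall-out as
#' defined alongside the other rates here, i.e. the fraction of
#' positive calls that are wrong, the complement of the precision),
#' precision `PPV = tp/(tp+fp)`, all in percent, plus the F-score
#' `tp/(tp + (fp+fn)/2)` and the Matthews correlation coefficient.
#' When a denominator vanishes the rate is returned as 0 with the
#' `degenerate` flag listing which.
#'
#' @param cm a `confusion_matrix`.
#' @param klass class name or code (0-4).
#' @return named list with `TPR`, `FNR`, `FPR`, `PPV` (percent), `F`,
#'   `MCC`, and `degenerate`.
#' @export
class_metrics <- function(cm, klass) {
  if (is.numeric(klass)) klass <- distortion_classes[klass + 1L]
  if (!klass %in% distortion_classes) stop("unknown class: ", klass)
  cmx <- matrix(as.numeric(unclass(cm)), 5, 5)
  i <- match(klass, distortion_classes)
  tp <- cmx[i, i]
  fp <- sum(cmx[-i, i])
  fn <- sum(cmx[i, -i])
  tn <- sum(cmx[-i, -i])
  degenerate <- character(0)
  rate <- function(num, den, nm) {
    if (den == 0) { degenerate <<- c(degenerate, nm); return(0) }
    100 * num / den
  }
  TPR <- rate(tp, tp + fn, "TPR")
  FNR <- rate(fn, tp + fn, "FNR")
  FPR <- rate(fp, tp + fp, "FPR")
  PPV <- rate(tp, tp + fp, "PPV")
  Fs <- if (tp + (fp + fn) / 2 == 0) { degenerate <- c(degenerate, "F"); 0 }
  else tp / (tp + (fp + fn) / 2)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  MCC <- if (den == 0) { degenerate <- c(degenerate, "MCC"); 0 }
  else (tp * tn - fp * fn) / sqrt(den)
  list(TPR = TPR, FNR = FNR, FPR = FPR, PPV = PPV, F = Fs, MCC = MCC,
       degenerate = degenerate)
}

#' Root-mean-square error between two sequences
#'
#' RMSE over all coordinates and samples:
#' `sqrt(mean((est - ref)^2))` across the `K = markers x 3` variables
#' and `N` frames.  Gap samples in either sequence are excluded.
#'
#' @param ref reference [mocap_sequence].
#' @param est estimated/reconstructed [mocap_sequence].
#' @return RMSE in mm.
#' @export
rmse <- function(ref, est) {
  if (!identical(dim(ref$positions), dim(est$positions)))
    stop("sequence shapes differ")
  d <- est$positions - ref$positions
  sqrt(mean(d^2, na.rm = TRUE))
}

#' Generic moving-statistics outlier baselines
#'
#' Two per-coordinate anomaly detectors used as comparison baselines:
#' `m3s` (moving three-sigma) flags samples deviating from the moving
#' mean by more than `k` moving standard deviations; `hampel` flags
#' deviations from the moving median beyond `k * 1.4826 * MAD` (the
#' Gaussian-consistent scaled median absolute deviation, floored at a
#' small epsilon).  Both consider each coordinate separately and are
#' blind to inter-marker structure.
#'
#' @param x numeric coordinate trajectory.
#' @param method `"m3s"` or `"hampel"`.
#' @param window odd moving-window length, samples.
#' @param k threshold multiplier.
#' @return logical outlier mask.
#' @export
baseline_detect <- function(x, method = c("m3s", "hampel"), window = 19,
                            k = 3) {
  method <- match.arg(method)
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  n <- length(x)
  h <- (window - 1) %/% 2
  if (method == "m3s") {
    mu <- moving_average(x, window)
    mu2 <- moving_average(x^2, window)
    sdv <- sqrt(pmax(mu2 - mu^2, 0))
    return(abs(x - mu) > k * sdv)
  }
  med <- moving_median(x, window)
  admed <- abs(x - med)
  madv <- moving_median(admed, window)
  scale <- pmax(1.4826 * madv, 1e-9 * max(stats::sd(x), 1))
  admed > k * scale
}

fold_seeds <- function(seed, folds) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, folds))
}

#' Synthetic classification experiment: contamination and detection
#'
#' Repeats generate -> contaminate -> classify -> score over seeded
#' folds and aggregates the per-sample confusion matrices.  The
#' averaged counts are reported both raw and rounded half away from
#' zero, together with per-class rates computed from the pooled
#' matrix.  Optionally scores the generic baselines on the same folds
#' (their binary outlier output is tallied against the same five-class
#' truth, every flagged sample counting as a detection of its true
#' class for sensitivity purposes, versus a binary "any artifact"
#' prediction column).
#'
#' @param folds number of simulation folds.
#' @param share distorted time share.
#' @param mu_amp mean distortion amplitude, mm.
#' @param seed master seed; fold seeds are derived from it.
#' @param base_cfg a [base_sequence_config] (seed overridden per fold).
#' @param params a [detector_params].
#' @param predictor an [ffnn_params].
#' @param baselines logical; also run `m3s` and `hampel` on each fold.
#' @param baseline_window window for the baselines.
#' @return list with `mean_cm` (raw averaged counts), `cm` (rounded),
#'   `pooled_cm` (summed), `metrics` (per-class list from the pooled
#'   matrix), and when requested `baselines` (per method: pooled 5x2
#'   truth-by-flagged table and per-class detection rates in percent).
#' @export
run_experiment_e1 <- function(folds = 50, share = 0.2, mu_amp = 10,
                              seed = 1L,
                              base_cfg = base_sequence_config(),
                              params = detector_params(),
                              predictor = ffnn_params(),
                              baselines = FALSE, baseline_window = 19) {
  stopifnot(folds >= 1)
  seeds <- fold_seeds(seed, folds)
  pooled <- matrix(0, 5, 5, dimnames = list(truth = distortion_classes,
                                            predicted = distortion_classes))
  bl <- list()
  if (baselines)
    bl <- list(m3s = matrix(0, 5, 2), hampel = matrix(0, 5, 2))
  for (f in seq_len(folds)) {
    bc <- base_cfg
    bc$seed <- seeds[f]
    gen <- generate_base_sequence(bc)
    cc <- contamination_config(share = share, mu_amp = mu_amp,
                               seed = seeds[f] + 1L)
    cont <- contaminate(gen$seq, cc)
    rep_ <- classify_sequence(cont$seq, gen$hier, params, predictor)
    tr <- truth_class_mask(cont$seq, cont$truth)
    pooled <- pooled + unclass(confusion(tr, rep_, cont$seq))
    if (baselines) {
      for (meth in names(bl)) {
        flag <- array(FALSE, dim = dim(tr))
        for (m in seq_len(n_markers(cont$seq))) for (c3 in 1:3)
          flag[, m, c3] <- baseline_detect(cont$seq$positions[, m, c3],
                                           meth, baseline_window)
        tf <- factor(distortion_classes[as.vector(tr) + 1L],
                     levels = distortion_classes)
        bl[[meth]] <- bl[[meth]] +
          table(tf, factor(as.vector(flag), levels = c(FALSE, TRUE)))
      }
    }
  }
  mean_cm <- pooled / folds
  out <- list(
    mean_cm = mean_cm,
    cm = structure(round_half_away(mean_cm), class = "confusion_matrix"),
    pooled_cm = structure(pooled, class = "confusion_matrix"),
    metrics = stats::setNames(lapply(distortion_classes, function(k)
      class_metrics(structure(pooled, class = "confusion_matrix"), k)),
      distortion_classes),
    folds = folds, share = share, mu_amp = mu_amp)
  if (baselines) {
    out$baselines <- lapply(bl, function(tab) {
      dimnames(tab) <- list(truth = distortion_classes,
                            flagged = c("no", "yes"))
      rates <- 100 * tab[, 2] / pmax(rowSums(tab), 1)
      list(table = tab, detection_rate = rates)
    })
  }
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Synthetic reconstruction experiment: detection plus repair
#'
#' For each artifact class separately, repeats contaminate (that class
#' only) -> classify -> repair with every method under (a) the
#' ground-truth intervals (perfect detection) and (b) the detected
#' intervals (actual classification), and averages the RMSE against
#' the clean sequence over folds.  One loose model per fold is fitted
#' on the signal bridged at the detected intervals and reused for both
#' detection arms of the FFNN repair.
#'
#' @param folds number of folds per class.
#' @param share distorted time share per fold.
#' @param mu_amp mean amplitude, mm.
#' @param methods repair methods to evaluate.
#' @param classes artifact classes to evaluate.
#' @param seed master seed.
#' @param base_cfg a [base_sequence_config].
#' @param params a [detector_params].
#' @param predictor an [ffnn_params].
#' @return data.frame with columns `klass`, `method` (including
#'   `"distorted"` for the no-repair reference), `detection`
#'   (`perfect`/`classified`/`none`) and `rmse` (mm, averaged over
#'   folds).
#' @export
run_experiment_e3 <- function(folds = 20, share = 0.1, mu_amp = 10,
                              methods = c("linear", "spline", "savgol",
                                          "ffnn"),
                              classes = c("peak", "heavy_noise", "step",
                                          "slow"),
                              seed = 1L,
                              base_cfg = base_sequence_config(
                                n_markers = 8, n_groups = 2,
                                duration_s = 30),
                              params = detector_params(),
                              predictor = ffnn_params()) {
  stopifnot(folds >= 1)
  seeds <- fold_seeds(seed, folds)
  acc <- list()
  add <- function(klass, method, detection, val) {
    key <- paste(klass, method, detection)
    if (is.null(acc[[key]]))
      acc[[key]] <<- list(klass = klass, method = method,
                          detection = detection, sum = 0, n = 0)
    acc[[key]]$sum <<- acc[[key]]$sum + val
    acc[[key]]$n <<- acc[[key]]$n + 1
  }
  for (klass in classes) for (f in seq_len(folds)) {
    bc <- base_cfg
    bc$seed <- seeds[f]
    gen <- generate_base_sequence(bc)
    cc <- contamination_config(share = share, mu_amp = mu_amp,
                               classes = klass, seed = seeds[f] + 1L)
    cont <- contaminate(gen$seq, cc)
    add(klass, "distorted", "none", rmse(gen$seq, cont$seq))
    rep_ <- classify_sequence(cont$seq, gen$hier, params, predictor)
    det_iv <- rep_$intervals
    truth_iv <- cont$truth
    models <- NULL
    if ("ffnn" %in% methods) {
      # one loose model per fold, fitted on the detection-bridged signal
      bridged <- cont$seq$positions
      for (i in seq_len(nrow(det_iv))) {
        dv <- det_iv[i, ]
        idx <- (dv$start + 1L):dv$end
        mk <- logical(n_frames(cont$seq)); mk[idx] <- TRUE
        bridged[, dv$marker, dv$coord + 1L] <-
          clean_intervals(bridged[, dv$marker, dv$coord + 1L], mk)
      }
      bseq <- mocap_sequence(bridged, cont$seq$labels, cont$seq$fps)
      need <- unique(c(det_iv$marker, truth_iv$marker))
      models <- lapply(need, function(m) {
        sub <- det_iv[det_iv$marker == m, ]
        flagged <- logical(n_frames(cont$seq))
        for (i in seq_len(nrow(sub)))
          flagged[(sub$start[i] + 1L):sub$end[i]] <- TRUE
        fit_loose_ffnn(bseq, gen$hier, m, predictor, exclude = flagged)
      })
      names(models) <- need
    }
    for (method in methods) {
      fixed_p <- repair(cont$seq, truth_iv, method, hier = gen$hier,
                        models = models, predictor = predictor)
      add(klass, method, "perfect", rmse(gen$seq, fixed_p))
      fixed_c <- repair(cont$seq, det_iv, method, hier = gen$hier,
                        models = models, predictor = predictor)
      add(klass, method, "classified", rmse(gen$seq, fixed_c))
    }
  }
  do.call(rbind, lapply(acc, function(a)
    data.frame(klass = a$klass, method = a$method, detection = a$detection,
               rmse = a$sum / a$n, stringsAsFactors = FALSE)))
}
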