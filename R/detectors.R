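#' Default parameters of the four detection stages
#'
#' All thresholds are expressed as multiples (`k1`, `k2`, `k3`, `kU`,
#' `khv`) of a dispersion estimate of the stage's own residual signal,
#' so they adapt to the scale of the data.  Window and length
#' parameters are in samples at the nominal 100 Hz rate.
#'
#' @param peaks list: `median_window` of the median high-pass (19),
#'   `k1` threshold multiplier on the differential (3),
#'   `amp_ratio_threshold` on the moving |sum|/sum ratio (5),
#'   `max_size` maximal expected peak width (5).
#' @param noise list: `k2` threshold multiplier (2), `min_len` minimal
#'   burst length (20), `sg_L`/`sg_M` Savitzky-Golay order and window
#'   (5, 13).
#' @param step list: `k3` threshold multiplier (3), `min_len` minimal
#'   step length (20), `max_dist` maximal edge-pair distance (200),
#'   `sg_L`/`sg_M` (5, 13).
#' @param slow list: `sg_L`/`sg_M` of the residual smoother (7, 11),
#'   `kU` upper (trigger) threshold multiplier (3), `tauU` minimal
#'   trigger run (20), `khv` lower (regrow) threshold multiplier (0.5),
#'   `tau_hv` minimal expanded length (50).
#' @return list of class `detector_params`.
#' @export
detector_params <- function(
    peaks = list(median_window = 19, k1 = 3, amp_ratio_threshold = 5,
                 max_size = 5),
    noise = list(k2 = 2, min_len = 20, sg_L = 5, sg_M = 13),
    step = list(k3 = 3, min_len = 20, max_dist = 200, sg_L = 5, sg_M = 13),
    slow = list(sg_L = 7, sg_M = 11, kU = 3, tauU = 20, khv = 0.5,
                tau_hv = 50)) {
  p <- list(peaks = peaks, noise = noise, step = step, slow = slow)
  thresholds <- c(peaks$k1, peaks$amp_ratio_threshold, noise$k2, step$k3,
                  slow$kU, slow$khv)
  if (any(thresholds <= 0)) stop("all threshold multipliers must be > 0")
  lens <- c(peaks$median_window, peaks$max_size, noise$min_len,
            step$min_len, step$max_dist, slow$tauU, slow$tau_hv)
  if (any(lens < 1 | lens != round(lens)))
    stop("window/length parameters must be positive integers")
  structure(p, class = "detector_params")
}

# centred moving sum over window of half-width h (edges shrink)
moving_sum <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  cs[pmin(n, i + h) + 1L] - cs[pmax(0L, i - h - 1L) + 1L]
}

# zero out runs of TRUE shorter than minlen
drop_short_runs <- function(mask, minlen) {
  r <- rle(mask)
  r$values[r$values & r$lengths < minlen] <- FALSE
  inverse.rle(r)
}

#' Detect isolated single peaks in one coordinate
#'
#' Stage 1 of the pipeline.  Low frequencies (legitimate motion) are
#' removed with a moving median; the differential of the remainder is
#' thresholded at `k1` standard deviations; moving sums over a window of
#' `2 * max_size + 3` samples form the ratio of the summed magnitudes to
#' the magnitude of the sum, which is large where opposite-signed
#' differential spikes cancel, i.e. at a peak; candidates with
#' `ratio > amp_ratio_threshold` are consolidated with a binary closing
#' and screened with a binary top-hat, both with a structuring element
#' equal to the moving-sum window, keeping only candidate clusters
#' isolated within that neighbourhood (clusters with close neighbours,
#' e.g. the fragmented candidates of a noise burst, belong to the
#' heavy-noise stage); the final
#' mask restricts those clusters to the samples whose median-filter
#' residual itself exceeds the threshold, so it covers the deviating
#' samples and not the surrounding detection window.
#'
#' @param x numeric coordinate trajectory (mm).
#' @param p a [detector_params] list (the `peaks` element is used).
#' @param sigma optional dispersion of the high-passed differential; by
#'   default estimated from `x` itself, while [classify_sequence] pools
#'   the estimate over all marker coordinates of the sequence.
#' @return logical per-frame mask.
#' @export
detect_peaks <- function(x, p = detector_params(), sigma = NULL) {
  pk <- p$peaks
  n <- length(x)
  if (n < max(pk$median_window, 2 * pk$max_size + 3)) return(logical(n))
  xhp <- x - moving_median(x, pk$median_window)
  d <- c(0, diff(xhp))
  if (is.null(sigma)) sigma <- stats::sd(d)
  if (!is.finite(sigma) || sigma == 0) return(logical(n))
  dt <- ifelse(abs(d) > pk$k1 * sigma, d, 0)
  h <- pk$max_size + 1L                      # window length 2*max_size + 3
  msum <- moving_sum(dt, h)
  msabs <- moving_sum(abs(dt), h)
  # perfectly antisymmetric peaks give msum == 0; floor the denominator
  ratio <- msabs / pmax(abs(msum), 1e-12 * sigma)
  cand <- ratio > pk$amp_ratio_threshold & msabs > 0
  # "isolated" means isolated within the structuring neighbourhood:
  # close nearby candidate fragments together first, then reject every
  # cluster the top-hat sees as wide (e.g. fragmented noise bursts)
  s <- 2L * pk$max_size + 3L
  iso <- morph1d(morph1d(cand, "close", s), "tophat", s)
  iso & cand & abs(xhp) > pk$k1 * sigma
}

#' Detect heavy-noise bursts in one coordinate
#'
#' Stage 2; assumes isolated peaks were already removed.  The
#' differential is Savitzky-Golay high-passed; a grayscale closing of
#' its magnitude with a structuring element of `2 * min_len - 1` samples
#' builds an envelope that stays high across a dense burst but falls
#' between sparse excursions; the envelope is thresholded at its own
#' median plus `k2` standard deviations of the high-passed differential
#' (the median centring keeps the rule scale-free: a closed envelope of
#' stationary noise sits about two standard deviations above zero by
#' itself, so thresholding the raw envelope would flag clean signal);
#' a binary closing fills holes, segments shorter than `min_len` are
#' rejected, and a kept segment must be dense (at least 30 percent of
#' samples) in raw differential exceedances, so that two isolated
#' spikes bridged by the closing (the edges of a step change) are not
#' claimed as a burst.
#'
#' @inheritParams detect_peaks
#' @return logical per-frame mask.
#' @export
detect_heavy_noise <- function(x, p = detector_params(), sigma = NULL) {
  np <- p$noise
  n <- length(x)
  if (n < max(np$sg_M, 2 * np$min_len - 1)) return(logical(n))
  d1 <- c(0, diff(x))
  dhp <- savgol(d1, np$sg_L, np$sg_M, "high")
  if (is.null(sigma)) sigma <- stats::sd(dhp)
  if (!is.finite(sigma) || sigma == 0) return(logical(n))
  s <- 2L * np$min_len - 1L
  env <- morph1d(abs(dhp), "close", s)
  raw <- env > stats::median(env) + np$k2 * sigma
  filled <- morph1d(raw, "close", s)
  mask <- drop_short_runs(filled, np$min_len)
  # the closing fills between any two spikes closer than the element
  # (e.g. the edges of a 20-40 sample step), so a kept segment must
  # also be dense in raw differential exceedances, which only genuine
  # bursts are
  exceed <- abs(dhp) > np$k2 * sigma
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    span <- starts[i]:ends[i]
    if (mean(exceed[span]) < 0.3) mask[span] <- FALSE
  }
  mask
}

#' Detect rectangular step changes in one coordinate
#'
#' Stage 3; assumes peaks and heavy noise were already removed.  A step
#' offset produces complementary spikes in the differential at its two
#' edges; the differential is Savitzky-Golay high-passed and scanned
#' with [find_derivate_pairs] for opposite excursions beyond
#' `k3 * sigma` separated by `min_len` to `max_dist` samples; the span
#' between a pair is the detected step.
#'
#' @inheritParams detect_peaks
#' @return logical per-frame mask.
#' @export
detect_step_changes <- function(x, p = detector_params(), sigma = NULL) {
  sp <- p$step
  n <- length(x)
  if (n < max(sp$sg_M, sp$min_len + 1)) return(logical(n))
  d1 <- c(0, diff(x))
  dhp <- savgol(d1, sp$sg_L, sp$sg_M, "high")
  if (is.null(sigma)) sigma <- stats::sd(dhp)
  if (!is.finite(sigma) || sigma == 0) return(logical(n))
  find_derivate_pairs(dhp, sp$k3 * sigma, sp$min_len, sp$max_dist)
}

#' Detect slow deviations from a loose-predictor residual
#'
#' Stage 4.  The residual of the loose neural predictor is smoothed
#' with a Savitzky-Golay low-pass; runs where the smoothed magnitude
#' exceeds the upper threshold `kU * sigma_R` for at least `tauU`
#' frames seed detections, which then regrow backwards and forwards
#' while the magnitude stays above the lower threshold `khv * sigma_R`
#' (hysteresis); regrown detections shorter than `tau_hv` frames are
#' discarded as predictor fluctuations.
#'
#' @param residual numeric residual of one coordinate (NAs allowed at
#'   frames without prediction context; they are treated as
#'   sub-threshold).
#' @param sigma_R residual standard deviation from the fitted model.
#' @param p a [detector_params] list (the `slow` element is used).
#' @return logical per-frame mask.
#' @export
detect_slow_changes <- function(residual, sigma_R, p = detector_params()) {
  sl <- p$slow
  n <- length(residual)
  if (!is.finite(sigma_R)) stop("`sigma_R` must be finite (model fitted?)")
  if (n < sl$sg_M || sigma_R <= 0) return(logical(n))
  r <- ifelse(is.finite(residual), residual, 0)
  sm <- savgol(r, sl$sg_L, sl$sg_M, "low")
  hi <- abs(sm) > sl$kU * sigma_R
  lo <- abs(sm) > sl$khv * sigma_R
  seeds <- drop_short_runs(hi, sl$tauU)
  if (!any(seeds)) return(logical(n))
  # expand every seeded run through the surrounding above-lower run
  lor <- rle(lo)
  ends <- cumsum(lor$lengths)
  starts <- ends - lor$lengths + 1L
  mask <- logical(n)
  for (i in which(lor$values)) {
    span <- starts[i]:ends[i]
    if (any(seeds[span]) && length(span) >= sl$tau_hv) mask[span] <- TRUE
  }
  mask
}

#' Replace masked samples by linear interpolation
#'
#' Masked spans are bridged linearly between the nearest unmasked
#' neighbours; masked spans touching a boundary are filled with the
#' nearest unmasked value.  Unmasked samples are returned untouched.
#'
#' @param x numeric vector.
#' @param mask logical mask of samples to replace.
#' @return numeric vector with masked samples replaced.
#' @export
clean_intervals <- function(x, mask) {
  stopifnot(length(mask) == length(x))
  if (!any(mask)) return(x)
  keep <- which(!mask)
  if (length(keep) == 0) stop("cannot interpolate a fully-masked sequence")
  if (length(keep) == 1L) { x[mask] <- x[keep]; return(x) }
  x[mask] <- stats::approx(keep, x[keep], xout = which(mask), rule = 2)$y
  x
}

distortion_classes <- c("clear", "peak", "heavy_noise", "step", "slow")

# logical mask (1-based frames) -> data.frame of 0-based half-open intervals
mask_to_intervals <- function(mask, marker, coord, klass) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0)
    return(data.frame(marker = character(0), coord = integer(0),
                      start = integer(0), end = integer(0),
                      klass = character(0), stringsAsFactors = FALSE))
  data.frame(marker = marker, coord = coord,
             start = starts[on] - 1L, end = ends[on],
             klass = klass, stringsAsFactors = FALSE)
}

#' Run the full staged detection pipeline on a sequence
#'
#' Stages run per coordinate of every marker, from the simplest artifact
#' to the hardest: isolated peaks, then heavy noise, then step changes,
#' each followed by interpolation of the detected spans so later stages
#' see a cleaned signal; finally a loose neural predictor is fitted per
#' marker on the cleaned sequence and its residual is scanned for slow
#' deviations.  Samples claimed by an earlier stage are never relabelled
#' by a later one.  The `k * sigma` thresholds of stages 1-3 use a
#' dispersion pooled over all marker coordinates of the sequence at that
#' stage, matching the use of one detector configuration per recording;
#' the slow stage uses each coordinate's own residual dispersion.
#'
#' True gaps are bridged linearly for processing and are not classified.
#'
#' @param seq a [mocap_sequence].
#' @param hier a [body_hierarchy] covering the sequence's markers.
#' @param params a [detector_params] list.
#' @param predictor an [ffnn_params] list for the slow-change predictor.
#' @return an object of class `detection_report`: `class_mask` (integer
#'   `frames x markers x 3` array, 0 = clear .. 4 = slow), `intervals`
#'   (data.frame of 0-based half-open [DistortionInterval]s), `sigma`
#'   (per-stage dispersion diagnostics) and `cleaned` (the sequence
#'   after all four stages' interpolation).
#' @export
classify_sequence <- function(seq, hier, params = detector_params(),
                              predictor = ffnn_params()) {
  missing_m <- setdiff(seq$labels, unlist(hier$groups))
  if (length(missing_m))
    stop("markers absent from hierarchy: ", paste(missing_m, collapse = ", "))
  nf <- n_frames(seq)
  nm <- n_markers(seq)
  pos <- seq$positions
  # bridge true gaps; they are excluded from classification downstream
  for (m in seq_len(nm)) for (c3 in 1:3) {
    g <- seq$gap_mask[, m]
    if (any(g)) pos[, m, c3] <- clean_intervals(pos[, m, c3], g)
  }
  cls <- array(0L, dim = c(nf, nm, 3),
               dimnames = list(NULL, seq$labels, c("x", "y", "z")))

  stage_masks <- function(detect, stat_fun) {
    stats_all <- numeric(0)
    for (m in seq_len(nm)) for (c3 in 1:3)
      stats_all <- c(stats_all, stat_fun(pos[, m, c3]))
    sigma <- stats::sd(stats_all)
    masks <- array(FALSE, dim = c(nf, nm, 3))
    for (m in seq_len(nm)) for (c3 in 1:3)
      masks[, m, c3] <- detect(pos[, m, c3], sigma)
    list(masks = masks, sigma = sigma)
  }
  stat_peak <- function(x) c(0, diff(x - moving_median(x, params$peaks$median_window)))
  stat_sg <- function(L, M) function(x) savgol(c(0, diff(x)), L, M, "high")

  s1 <- stage_masks(function(x, s) detect_peaks(x, params, s), stat_peak)
  apply_stage <- function(masks, code) {
    for (m in seq_len(nm)) for (c3 in 1:3) {
      k <- masks[, m, c3] & cls[, m, c3] == 0L
      if (any(k)) {
        cls[, m, c3][k] <<- code
        pos[, m, c3] <<- clean_intervals(pos[, m, c3], masks[, m, c3])
      }
    }
  }
  apply_stage(s1$masks, 1L)
  s2 <- stage_masks(function(x, s) detect_heavy_noise(x, params, s),
                    stat_sg(params$noise$sg_L, params$noise$sg_M))
  apply_stage(s2$masks, 2L)
  s3 <- stage_masks(function(x, s) detect_step_changes(x, params, s),
                    stat_sg(params$step$sg_L, params$step$sg_M))
  apply_stage(s3$masks, 3L)

  cleaned <- mocap_sequence(pos, seq$labels, seq$fps, seq$gap_mask)
  sigma_R <- matrix(NA_real_, nm, 3,
                    dimnames = list(seq$labels, c("x", "y", "z")))
  m4 <- array(FALSE, dim = c(nf, nm, 3))
  for (m in seq_len(nm)) {
    flagged <- apply(cls[, m, , drop = FALSE] != 0L, 1, any)
    model <- fit_loose_ffnn(cleaned, hier, seq$labels[m], predictor,
                            exclude = flagged)
    res <- predict_residual(model, cleaned)
    # thresholds calibrate on the robust residual scale: the slow
    # artifacts to be detected are still present in the fitting window
    # and would inflate a plain standard deviation, raising their own
    # detection thresholds
    sigma_R[m, ] <- model$sigma_robust_coord
    for (c3 in 1:3)
      m4[, m, c3] <- detect_slow_changes(res[, c3], sigma_R[m, c3], params)
  }
  apply_stage(m4, 4L)

  # gaps carry no classification
  for (m in seq_len(nm)) cls[seq$gap_mask[, m], m, ] <- 0L

  iv <- list()
  for (m in seq_len(nm)) for (c3 in 1:3) for (code in 1:4) {
    mk <- cls[, m, c3] == code
    if (any(mk))
      iv[[length(iv) + 1L]] <- mask_to_intervals(
        mk, seq$labels[m], c3 - 1L, distortion_classes[code + 1L])
  }
  intervals <- if (length(iv)) do.call(rbind, iv) else
    mask_to_intervals(logical(nf), character(0), integer(0), character(0))

  structure(list(class_mask = cls, intervals = intervals,
                 sigma = list(peak = s1$sigma, noise = s2$sigma,
                              step = s3$sigma, slow = sigma_R),
                 cleaned = cleaned, params = params),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  tab <- table(factor(distortion_classes[x$class_mask + 1L],
                      levels = distortion_classes))
  cat("detection_report\n  samples per class:\n")
  print(tab)
  cat(sprintf("  %d intervals; stage sigmas: peak %.3g, noise %.3g, step %.3g\n",
              nrow(x$intervals), x$sigma$peak, x$sigma$noise, x$sigma$step))
  invisible(x)
}
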