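#' Configuration of the synthetic quasi-static base sequence
#'
#' The generator emulates a quasi-static capture subject (an actor
#' holding a pose with slow postural sway): markers are clustered into
#' rigid-ish groups; each group follows a smooth low-frequency
#' trajectory inherited from its parent group plus its own smaller
#' sway; members sit at fixed offsets with a small smooth deformation
#' and white sensor noise, plus sparse sub-millimetre reconstruction
#' jitter, the occasional one-sample flicker that survives even in
#' cleaned optical captures.  Within-group coordinates are therefore
#' highly correlated by construction.
#'
#' @param n_markers total marker count (divided evenly over groups).
#' @param n_groups number of body-segment groups (a root plus children).
#' @param fps sampling rate, Hz.
#' @param duration_s sequence length, seconds.
#' @param motion_amplitude peak-ish amplitude of the postural sway per
#'   axis, mm.
#' @param sensor_noise_sd white measurement noise, mm.
#' @param deformation_amplitude amplitude of the smooth per-marker
#'   deformation violating perfect rigidity, mm.
#' @param jitter_rate per-sample probability of a reconstruction
#'   jitter flicker.
#' @param jitter_sd standard deviation of a jitter flicker, mm.
#' @param seed RNG seed; the generated sequence is a deterministic
#'   function of the config.
#' @return list of class `base_sequence_config`.
#' @export
base_sequence_config <- function(n_markers = 16, n_groups = 4, fps = 100,
                                 duration_s = 60, motion_amplitude = 30,
                                 sensor_noise_sd = 0.3,
                                 deformation_amplitude = 1,
                                 jitter_rate = 0.005, jitter_sd = 1,
                                 seed = 1L) {
  stopifnot(n_markers >= 2, n_groups >= 1, n_markers %% n_groups == 0,
            fps > 0, duration_s > 0, sensor_noise_sd >= 0,
            motion_amplitude >= 0)
  structure(list(n_markers = n_markers, n_groups = n_groups, fps = fps,
                 duration_s = duration_s,
                 motion_amplitude = motion_amplitude,
                 sensor_noise_sd = sensor_noise_sd,
                 deformation_amplitude = deformation_amplitude,
                 jitter_rate = jitter_rate, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "base_sequence_config")
}

# smooth low-frequency trajectory: three sinusoids in 0.05-0.5 Hz,
# scaled to the requested amplitude
smooth_sway <- function(n, fps, amplitude) {
  t <- seq_len(n) / fps
  f <- stats::runif(3, 0.05, 0.5)
  ph <- stats::runif(3, 0, 2 * pi)
  a <- stats::runif(3, 0.3, 1)
  s <- a[1] * sin(2 * pi * f[1] * t + ph[1]) +
    a[2] * sin(2 * pi * f[2] * t + ph[2]) +
    a[3] * sin(2 * pi * f[3] * t + ph[3])
  amplitude * s / max(stats::sd(s), 1e-9) / 3
}

#' Generate a synthetic correlated base sequence with its hierarchy
#'
#' @param cfg a [base_sequence_config].
#' @return list with `seq` (a clean [mocap_sequence]) and `hier` (the
#'   matching [body_hierarchy]; the first group is the root, the others
#'   are its children).
#' @export
generate_base_sequence <- function(cfg = base_sequence_config()) {
  n <- round(cfg$duration_s * cfg$fps)
  per <- cfg$n_markers / cfg$n_groups
  if (per < 2)
    stop("need at least 2 markers per group for sibling-based prediction")
  with_local_seed(cfg$seed, {
    gnames <- paste0("seg", seq_len(cfg$n_groups))
    # root sway; children inherit it plus a smaller own component
    root_traj <- vapply(1:3, function(c3)
      smooth_sway(n, cfg$fps, cfg$motion_amplitude), numeric(n))
    group_traj <- vector("list", cfg$n_groups)
    group_origin <- vector("list", cfg$n_groups)
    for (g in seq_len(cfg$n_groups)) {
      own <- if (g == 1) 0 else vapply(1:3, function(c3)
        smooth_sway(n, cfg$fps, 0.3 * cfg$motion_amplitude), numeric(n))
      group_traj[[g]] <- root_traj + own
      group_origin[[g]] <- if (g == 1) c(0, 0, 1000) else
        c(0, 0, 1000) + stats::runif(3, -400, 400)
    }
    labels <- character(cfg$n_markers)
    pos <- array(NA_real_, c(n, cfg$n_markers, 3))
    groups <- list()
    idx <- 0L
    for (g in seq_len(cfg$n_groups)) {
      members <- character(per)
      for (j in seq_len(per)) {
        idx <- idx + 1L
        lab <- sprintf("M%02d_%s", idx, gnames[g])
        members[j] <- lab
        labels[idx] <- lab
        offset <- stats::runif(3, -150, 150)
        deform <- vapply(1:3, function(c3)
          smooth_sway(n, cfg$fps, cfg$deformation_amplitude), numeric(n))
        noise <- matrix(stats::rnorm(3 * n, 0, cfg$sensor_noise_sd), n, 3)
        jit <- matrix(0, n, 3)
        nj <- stats::rbinom(1, 3 * n, cfg$jitter_rate)
        if (nj > 0) {
          at <- sample.int(3 * n, nj)
          jit[at] <- stats::rnorm(nj, 0, cfg$jitter_sd)
        }
        pos[, idx, ] <- group_traj[[g]] +
          matrix(rep(group_origin[[g]] + offset, each = n), n) +
          deform + noise + jit
      }
      groups[[gnames[g]]] <- members
    }
    parents <- as.list(stats::setNames(rep(gnames[1], cfg$n_groups - 1),
                                       gnames[-1]))
    list(seq = mocap_sequence(pos, labels, cfg$fps),
         hier = body_hierarchy(groups, parents))
  })
}

#' Inject one distortion of a given class into a coordinate
#'
#' Shapes follow the four-class taxonomy: `peak` adds a constant
#' deviation of the given amplitude over a 1-to-few-sample interval;
#' `heavy_noise` adds white Gaussian noise whose standard deviation is
#' the amplitude; `step` adds a rectangular constant offset;
#' `slow` adds a symmetric triangular ramp peaking at the amplitude at
#' mid-interval.  The amplitude carries its sign as drawn (irrelevant
#' for heavy noise).
#'
#' @param x numeric coordinate trajectory.
#' @param klass one of `"peak"`, `"heavy_noise"`, `"step"`, `"slow"`.
#' @param start 0-based start frame of the half-open interval.
#' @param length interval length in samples.
#' @param amplitude signed amplitude in mm (noise standard deviation
#'   for `heavy_noise`).
#' @return the distorted coordinate vector.
#' @export
inject_distortion <- function(x, klass, start, length, amplitude) {
  klass <- match.arg(klass, distortion_classes[-1])
  if (start < 0 || length < 1 || start + length > base::length(x))
    stop("distortion interval [", start, ", ", start + length,
         ") out of range")
  i <- (start + 1L):(start + length)
  x[i] <- x[i] + switch(
    klass,
    peak = amplitude,
    heavy_noise = stats::rnorm(length, 0, abs(amplitude)),
    step = amplitude,
    slow = amplitude * (1 - abs(2 * seq(0, 1, length.out = length) - 1)))
  x
}

#' Configuration of the artifact contamination procedure
#'
#' @param share fraction of the sequence's time to distort (a
#'   distortion is active on some marker coordinate during that fraction
#'   of frames; at most one distortion at a time).
#' @param mu_amp mean distortion amplitude, mm.
#' @param sigma_amp amplitude standard deviation, mm (default
#'   `0.4 * mu_amp`).
#' @param mean_duration mean duration of bulk distortions, samples.
#' @param classes artifact classes to inject.
#' @param peak_max_len maximal single-peak width, samples.
#' @param margin minimal clear gap kept between bulk distortions,
#'   samples.
#' @param peak_margin minimal clear gap around seeded peaks, samples;
#'   peaks are isolated by definition of the class, and the default is
#'   the peak detector's own isolation neighbourhood
#'   (`2 * max_size + 3`).
#' @param seed RNG seed.
#' @return list of class `contamination_config`.
#' @export
contamination_config <- function(share = 0.2, mu_amp = 10,
                                 sigma_amp = 0.4 * mu_amp,
                                 mean_duration = 50,
                                 classes = c("peak", "heavy_noise",
                                             "step", "slow"),
                                 peak_max_len = 3, margin = 10,
                                 peak_margin = 13, seed = 1L) {
  stopifnot(share >= 0, share < 1, mu_amp > 0, sigma_amp >= 0,
            mean_duration > 0, peak_max_len >= 1)
  classes <- match.arg(classes, distortion_classes[-1], several.ok = TRUE)
  structure(list(share = share, mu_amp = mu_amp, sigma_amp = sigma_amp,
                 mean_duration = mean_duration, classes = classes,
                 peak_max_len = peak_max_len, margin = margin,
                 peak_margin = peak_margin, seed = as.integer(seed)),
            class = "contamination_config")
}

draw_amplitude <- function(mu, sigma) {
  repeat {
    a <- stats::rnorm(1, mu, sigma)
    if (a > 0) break
  }
  a * sample(c(-1, 1), 1)
}

#' Contaminate a clean sequence with logged artificial distortions
#'
#' Bulk distortions (heavy noise, step and slow changes) are placed
#' first: per enabled class, durations are drawn from an exponential
#' distribution with the configured mean (a Poisson process in time)
#' until the class reaches an equal share of the distorted-time budget
#' `share * n_frames`; each event lands on a uniformly drawn marker
#' coordinate and a uniformly drawn position such that no two
#' distortions overlap in time anywhere in the sequence.  Isolated
#' peaks (1 to `peak_max_len` samples wide) are seeded afterwards in
#' untouched regions with a clear margin on both sides.  Amplitudes are
#' Gaussian with a random sign.  Every injection is logged.
#'
#' @param seq a clean [mocap_sequence].
#' @param cfg a [contamination_config].
#' @return list with `seq` (the contaminated sequence) and `truth`
#'   (data.frame of 0-based half-open intervals: `marker`, `coord`,
#'   `start`, `end`, `klass`, `amplitude`).
#' @export
contaminate <- function(seq, cfg = contamination_config()) {
  n <- n_frames(seq)
  nm <- n_markers(seq)
  budget_class <- cfg$share * n / length(cfg$classes)
  with_local_seed(cfg$seed, {
    occupied <- logical(n)     # global one-at-a-time timeline
    truth <- list()
    place <- function(len, margin) {
      # uniformly drawn start avoiding occupied frames (with margin)
      lo <- max(0L, margin)
      for (try in 1:200) {
        s <- sample.int(n - len - 2L * lo + 1L, 1L) - 1L + lo
        span <- (s - margin + 1L):(s + len + margin)
        span <- span[span >= 1L & span <= n]
        if (!any(occupied[span])) {
          occupied[(s + 1L):(s + len)] <<- TRUE
          return(s)
        }
      }
      NA_integer_
    }
    add_event <- function(klass, len, margin) {
      s <- place(len, margin)
      if (is.na(s)) return(FALSE)
      amp <- draw_amplitude(cfg$mu_amp, cfg$sigma_amp)
      m <- sample.int(nm, 1L)
      c3 <- sample.int(3L, 1L)
      truth[[length(truth) + 1L]] <<- data.frame(
        marker = seq$labels[m], coord = c3 - 1L, start = s, end = s + len,
        klass = klass, amplitude = amp, stringsAsFactors = FALSE)
      TRUE
    }
    bulk <- intersect(c("heavy_noise", "step", "slow"), cfg$classes)
    for (klass in bulk) {
      placed <- 0
      fails <- 0L
      while (placed < budget_class && fails < 50L) {
        len <- max(4L, round(stats::rexp(1, 1 / cfg$mean_duration)))
        len <- min(len, n %/% 4L)
        if (add_event(klass, len, cfg$margin)) placed <- placed + len
        else fails <- fails + 1L
      }
      if (placed < budget_class)
        warning("could not place the full ", klass,
                " budget (share too large?)")
    }
    if ("peak" %in% cfg$classes) {
      placed <- 0
      fails <- 0L
      while (placed < budget_class && fails < 1000L) {
        len <- sample.int(cfg$peak_max_len, 1L)
        if (add_event("peak", len, cfg$peak_margin)) placed <- placed + len
        else fails <- fails + 1L
      }
      if (placed < budget_class)
        warning("could not place the full peak budget (share too large?)")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(marker = character(0), coord = integer(0),
                 start = integer(0), end = integer(0),
                 klass = character(0), amplitude = numeric(0),
                 stringsAsFactors = FALSE)
    pos <- seq$positions
    for (i in seq_len(nrow(truth))) {
      tv <- truth[i, ]
      pos[, tv$marker, tv$coord + 1L] <- inject_distortion(
        pos[, tv$marker, tv$coord + 1L], tv$klass, tv$start,
        tv$end - tv$start, tv$amplitude)
    }
    list(seq = mocap_sequence(pos, seq$labels, seq$fps, seq$gap_mask),
         truth = truth)
  })
}
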