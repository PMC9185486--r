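#' Repair detected artifact intervals in a sequence
#'
#' Applies one of four reconstruction methods inside the given
#' intervals only; outside them the signal passes through bit-identical.
#'
#' * `linear` — linear interpolation across each interval from the
#'   flanking clean samples.
#' * `spline` — natural cubic spline through flanking clean context of
#'   twice the interval length on each side.
#' * `savgol` — the interval is replaced by the output of a
#'   Savitzky-Golay filter (order 13, window 101 by default) computed
#'   on the distorted signal itself; the filter averages short or
#'   zero-mean distortions away but follows long offsets, so it
#'   repairs noise bursts well and step/slow changes hardly at all.
#' * `ffnn` — the interval is replaced by the loose neural predictor's
#'   replica-averaged prediction; models are fitted once per sequence
#'   per marker on the signal with the intervals bridged linearly, or
#'   supplied ready-made via `models`.
#'
#' Intervals touching a sequence boundary fall back to nearest-value
#' filling where no flank exists.
#'
#' @param seq the distorted [mocap_sequence].
#' @param intervals a `detection_report` or a data.frame of 0-based
#'   half-open intervals with columns `marker`, `coord`, `start`, `end`.
#' @param method one of `"linear"`, `"spline"`, `"savgol"`, `"ffnn"`.
#' @param hier a [body_hierarchy]; required for `method = "ffnn"`.
#' @param models optional named list of fitted `predictor_model`s per
#'   marker (reused instead of refitting).
#' @param sg_order,sg_window Savitzky-Golay repair parameters.
#' @param predictor an [ffnn_params] list used when fitting repair
#'   models.
#' @return the repaired [mocap_sequence].
#' @export
repair <- function(seq, intervals,
                   method = c("linear", "spline", "savgol", "ffnn"),
                   hier = NULL, models = NULL,
                   sg_order = 13, sg_window = 101,
                   predictor = ffnn_params()) {
  method <- match.arg(method)
  iv <- if (inherits(intervals, "detection_report")) intervals$intervals
  else intervals
  stopifnot(all(c("marker", "coord", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0) return(seq)
  if (any(iv$start < 0 | iv$end > n_frames(seq) | iv$start >= iv$end))
    stop("invalid repair interval")
  pos <- seq$positions
  n <- n_frames(seq)
  coord_mask <- function(sub) {
    mk <- logical(n)
    for (i in seq_len(nrow(sub))) mk[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    mk
  }
  if (method == "ffnn") {
    if (is.null(hier) && is.null(models))
      stop("`ffnn` repair needs a hierarchy (or pre-fitted models)")
    bridged <- pos
    for (m in unique(iv$marker)) for (c3 in 0:2) {
      sub <- iv[iv$marker == m & iv$coord == c3, ]
      if (nrow(sub))
        bridged[, m, c3 + 1L] <- clean_intervals(pos[, m, c3 + 1L],
                                                 coord_mask(sub))
    }
    bseq <- mocap_sequence(bridged, seq$labels, seq$fps, seq$gap_mask)
    if (is.null(models)) {
      models <- lapply(unique(iv$marker), function(m) {
        sub <- iv[iv$marker == m, ]
        flagged <- logical(n)
        for (i in seq_len(nrow(sub)))
          flagged[(sub$start[i] + 1L):sub$end[i]] <- TRUE
        fit_loose_ffnn(bseq, hier, m, predictor, exclude = flagged)
      })
      names(models) <- unique(iv$marker)
    }
    for (m in unique(iv$marker)) {
      if (is.null(models[[m]]))
        stop("no fitted model supplied for marker ", m)
      pred <- predict_positions(models[[m]], bseq)
      for (c3 in 0:2) {
        sub <- iv[iv$marker == m & iv$coord == c3, ]
        if (nrow(sub) == 0) next
        mk <- coord_mask(sub) & !is.na(pred[, c3 + 1L])
        pos[mk, m, c3 + 1L] <- pred[mk, c3 + 1L]
      }
    }
    return(mocap_sequence(pos, seq$labels, seq$fps, seq$gap_mask))
  }
  for (m in unique(iv$marker)) for (c3 in 0:2) {
    sub <- iv[iv$marker == m & iv$coord == c3, ]
    if (nrow(sub) == 0) next
    x <- pos[, m, c3 + 1L]
    mk <- coord_mask(sub)
    pos[, m, c3 + 1L] <- switch(
      method,
      linear = clean_intervals(x, mk),
      spline = repair_spline(x, sub),
      savgol = {
        sg <- savgol(x, sg_order, sg_window, "low")
        x[mk] <- sg[mk]
        x
      })
  }
  mocap_sequence(pos, seq$labels, seq$fps, seq$gap_mask)
}

repair_spline <- function(x, sub) {
  n <- length(x)
  for (i in seq_len(nrow(sub))) {
    s <- sub$start[i] + 1L
    e <- sub$end[i]            # 1-based inclusive span s..e
    len <- e - s + 1L
    left <- seq.int(max(1L, s - 2L * len), s - 1L)
    right <- seq.int(e + 1L, min(n, e + 2L * len))
    ctx <- c(left[left >= 1], right[right <= n])
    if (length(ctx) < 2L) {             # boundary with no flank
      near <- if (length(ctx)) ctx[1] else NA
      x[s:e] <- if (is.na(near)) x[s:e] else x[near]
      next
    }
    x[s:e] <- stats::spline(ctx, x[ctx], xout = s:e, method = "natural")$y
  }
  x
}
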