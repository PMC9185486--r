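#' One-dimensional morphological operations
#'
#' Flat (linear, centred) structuring elements on 1-D signals.  Erosion
#' is the windowed minimum and dilation the windowed maximum; opening is
#' erosion followed by dilation, closing the reverse; the top-hat is the
#' signal minus its opening and so isolates features narrower than the
#' structuring element.  Edges are handled by replicate padding, which
#' makes constants fixed points of all four basic operations.  Logical
#' input yields logical output.
#'
#' @param x numeric or logical vector.
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`,
#'   `"tophat"`.
#' @param s structuring-element length in samples; odd, >= 1.
#' @return vector of the same length (and type class) as `x`.
#' @export
morph1d <- function(x, op = c("erode", "dilate", "open", "close", "tophat"),
                    s) {
  op <- match.arg(op)
  h <- struct_halfwidth(s)
  logical_in <- is.logical(x)
  v <- as.numeric(x)
  out <- switch(op,
                erode  = run_extreme(v, h, pmin),
                dilate = run_extreme(v, h, pmax),
                open   = run_extreme(run_extreme(v, h, pmin), h, pmax),
                close  = run_extreme(run_extreme(v, h, pmax), h, pmin),
                tophat = v - run_extreme(run_extreme(v, h, pmin), h, pmax))
  if (logical_in) out > 0.5 else out
}

struct_halfwidth <- function(s) {
  if (length(s) != 1L || !is.finite(s) || s < 1 || s %% 2 != 1)
    stop("structuring element length must be a positive odd integer")
  (as.integer(s) - 1L) %/% 2L
}

# windowed min/max by iterated pairwise reduction over shifted copies;
# replicate padding at both ends
run_extreme <- function(x, h, f) {
  n <- length(x)
  if (n == 0L || h == 0L) return(x)
  out <- x
  for (j in seq_len(min(h, n))) {
    lagj <- c(rep(x[1], j), x[seq_len(n - j)])
    leadj <- c(x[seq.int(1 + j, n)], rep(x[n], j))
    out <- f(out, lagj, leadj)
  }
  out
}

#' Scan a differential signal for opponent peak pairs
#'
#' Marks spans bounded by complementary differential excursions: a
#' positive excursion beyond `+threshold` paired with the first
#' subsequent negative excursion beyond `-threshold` (or vice versa)
#' within `maxlen` samples.  A rectangular offset of amplitude `A`
#' produces exactly such a `+A`/`-A` pair at its edges.
#'
#' Contiguous above-threshold samples within a small gap (half the
#' default Savitzky-Golay window, 6 samples) are consolidated into one
#' peak event at the sample of largest magnitude, carrying its sign.
#' This absorbs the ringing a high-pass filter leaves around a single
#' large excursion.  A consolidated event is kept only if its sign
#' dominates: a genuine step edge is a unipolar differential excursion
#' (its filter ringing is several times weaker), whereas a one-sample
#' displacement produces a balanced `+/-` doublet whose extrema are
#' comparable; events whose extremum is less than `dominance` times
#' the opposite-sign extremum are discarded as doublets, they belong
#' to the peak detector.  Peaks are then paired left-to-right: each peak
#' participates in at most one pairing attempt with the first opposite
#' peak within `maxlen`; the pair is marked only when its extent `d`
#' satisfies `minlen <= d <= maxlen`.  Marked spans are half-open
#' `[i, j+1)` over the peak positions `i < j`.
#'
#' @param dx numeric differential signal.
#' @param threshold positive excursion threshold.
#' @param minlen minimal pair distance in samples.
#' @param maxlen maximal pair distance (search horizon) in samples.
#' @param merge_gap consolidation gap for peak clusters, samples.
#' @param dominance minimal ratio of a cluster's extremum to its
#'   opposite-sign extremum for the cluster to count as a unipolar
#'   edge.
#' @return logical mask of the same length as `dx`.
#' @export
find_derivate_pairs <- function(dx, threshold, minlen, maxlen,
                                merge_gap = 6L, dominance = 2) {
  stopifnot(threshold > 0, minlen > 0, minlen <= maxlen)
  n <- length(dx)
  mask <- logical(n)
  exc <- which(is.finite(dx) & abs(dx) > threshold)
  if (length(exc) < 2L) return(mask)
  # consolidate excursions separated by <= merge_gap into peak events
  brk <- which(diff(exc) > merge_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(exc))
  pos <- integer(0)
  sgn <- integer(0)
  for (i in seq_along(starts)) {
    idx <- exc[starts[i]:ends[i]]
    top <- idx[which.max(abs(dx[idx]))]
    # unipolarity: compare against the strongest opposite-sign value in
    # the raw signal across the cluster's extent (plus the merge gap),
    # not just other exceedances
    win <- max(1L, min(idx) - merge_gap):min(n, max(idx) + merge_gap)
    oppv <- dx[win][sign(dx[win]) == -sign(dx[top])]
    if (length(oppv) && abs(dx[top]) < dominance * max(abs(oppv))) next
    pos <- c(pos, top)
    sgn <- c(sgn, sign(dx[top]))
  }
  if (length(pos) < 2L) return(mask)
  used <- logical(length(pos))
  for (i in seq_along(pos)) {
    if (used[i]) next
    j <- i + 1L
    partner <- 0L
    while (j <= length(pos) && pos[j] - pos[i] <= maxlen) {
      if (!used[j] && sgn[j] == -sgn[i]) { partner <- j; break }
      j <- j + 1L
    }
    if (partner == 0L) next
    d <- pos[partner] - pos[i]
    # the first opposite peak is this peak's one pairing attempt
    used[i] <- TRUE
    used[partner] <- TRUE
    if (d >= minlen && d <= maxlen)
      mask[pos[i]:pos[partner]] <- TRUE
  }
  mask
}
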