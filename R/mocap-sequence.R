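#' Construct a motion-capture sequence
#'
#' A `mocap_sequence` holds the 3-D trajectories of a set of labelled
#' markers sampled at a fixed rate: a `frames x markers x 3` array of
#' positions in millimetres, plus a per-marker, per-frame gap mask for
#' samples the capture system failed to reconstruct.
#'
#' Frame indices are 0-based and all intervals over frames are half-open
#' `[start, end)`, so that interval arithmetic composes with masks without
#' off-by-one corrections.
#'
#' @param positions numeric array `frames x markers x 3` (millimetres).
#' @param labels character vector of marker names, one per marker.
#' @param fps sampling rate in Hz (must be > 0).
#' @param gap_mask optional logical `frames x markers` matrix, `TRUE` where
#'   the sample is missing.  Non-finite positions are absorbed into the gap
#'   mask automatically.
#' @return an object of class `mocap_sequence`.
#' @export
mocap_sequence <- function(positions, labels, fps, gap_mask = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("`positions` must be a frames x markers x 3 array")
  nf <- dim(positions)[1]
  nm <- dim(positions)[2]
  labels <- as.character(labels)
  if (length(labels) != nm)
    stop("length(labels) must equal the number of markers")
  if (anyDuplicated(labels))
    stop("marker labels must be unique")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  if (is.null(gap_mask)) gap_mask <- matrix(FALSE, nf, nm)
  if (!is.logical(gap_mask) || !all(dim(gap_mask) == c(nf, nm)))
    stop("`gap_mask` must be a logical frames x markers matrix")
  nonfinite <- apply(positions, c(1, 2), function(v) any(!is.finite(v)))
  gap_mask <- gap_mask | nonfinite
  if (any(gap_mask)) {
    # gaps carry no coordinates; normalise their storage to NA
    for (m in seq_len(nm)) positions[gap_mask[, m], m, ] <- NA_real_
  }
  dimnames(positions) <- list(NULL, labels, c("x", "y", "z"))
  colnames(gap_mask) <- labels
  structure(
    list(labels = labels, fps = fps, positions = positions,
         gap_mask = gap_mask),
    class = "mocap_sequence"
  )
}

#' @export
print.mocap_sequence <- function(x, ...) {
  cat(sprintf("mocap_sequence: %d frames x %d markers @ %g Hz (%.2f s)\n",
              n_frames(x), n_markers(x), x$fps, n_frames(x) / x$fps))
  cat(sprintf("  markers: %s\n",
              paste(utils::head(x$labels, 8), collapse = ", ")))
  ng <- sum(x$gap_mask)
  if (ng > 0) cat(sprintf("  gaps: %d marker-frames\n", ng))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `mocap_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$positions)[1]

#' Number of markers in a sequence
#' @param seq a `mocap_sequence`.
#' @return integer marker count.
#' @export
n_markers <- function(seq) dim(seq$positions)[2]

#' Extract one marker's trajectory
#' @param seq a `mocap_sequence`.
#' @param marker marker name.
#' @return numeric `frames x 3` matrix with columns x, y, z.
#' @export
marker_xyz <- function(seq, marker) {
  if (!marker %in% seq$labels) stop("unknown marker: ", marker)
  seq$positions[, marker, , drop = TRUE]
}

#' Read a motion-capture sequence from disk
#'
#' Two plain-text dialects are supported.  `"csv"` is one row per frame
#' with columns `<marker>_x`, `<marker>_y`, `<marker>_z` preceded by a
#' `# fps=<rate>` metadata line; empty fields are gaps.  `"trc"` is the
#' standard mocap TRC layout (tab-separated, five header lines, frame
#' number and time columns, then X/Y/Z triples); empty fields are gaps.
#' C3D is a binary format outside the scope of this build; requesting it
#' raises an informative error so the reader interface stays uniform.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"trc"`, `"c3d"`; default guessed from
#'   the file extension.
#' @return a [mocap_sequence].
#' @export
load_sequence <- function(path, format = c("auto", "csv", "trc", "c3d")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", trc = "trc", c3d = "c3d",
                     stop("cannot guess format from extension of ", path))
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_mocap_csv(path),
         trc = read_mocap_trc(path),
         c3d = stop("C3D reading is not supported by this build; ",
                    "export to TRC or CSV"))
}

#' Write a motion-capture sequence to disk
#'
#' Gap samples are serialised as the dialect's missing token (an empty
#' field), never as zeros.  `load_sequence(save_sequence(x))` round-trips
#' to write precision.
#'
#' @param seq a [mocap_sequence].
#' @param path output file path.
#' @param format `"csv"` or `"trc"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
save_sequence <- function(seq, path, format = c("auto", "csv", "trc")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", trc = "trc",
                     stop("cannot guess format from extension of ", path))
  switch(format,
         csv = write_mocap_csv(seq, path),
         trc = write_mocap_trc(seq, path))
  invisible(path)
}

fmt_num <- function(v) {
  out <- formatC(v, format = "g", digits = 10)
  out[!is.finite(v)] <- ""
  out
}

flatten_positions <- function(seq) {
  nf <- n_frames(seq)
  cols <- lapply(seq$labels, function(m) seq$positions[, m, , drop = TRUE])
  mat <- do.call(cbind, cols)
  colnames(mat) <- as.vector(t(outer(seq$labels, c("x", "y", "z"),
                                     paste, sep = "_")))
  mat
}

write_mocap_csv <- function(seq, path) {
  mat <- flatten_positions(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%g", seq$fps), con)
  writeLines(paste(colnames(mat), collapse = ","), con)
  if (nrow(mat) > 0) {
    body <- apply(mat, 1, function(r) paste(fmt_num(r), collapse = ","))
    writeLines(body, con)
  }
}

read_mocap_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !grepl("^#\\s*fps=", lines[1]))
    stop("CSV mocap file must start with a '# fps=' line: ", path)
  fps <- as.numeric(sub("^#\\s*fps=", "", lines[1]))
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (!all(grepl("_(x|y|z)$", header)))
    stop("CSV header columns must be <marker>_x/_y/_z")
  labels <- unique(sub("_(x|y|z)$", "", header))
  expected <- as.vector(t(outer(labels, c("x", "y", "z"), paste, sep = "_")))
  if (!identical(header, expected))
    stop("CSV columns must come in x,y,z triples per marker")
  body <- lines[-(1:2)]
  nf <- length(body)
  mat <- matrix(NA_real_, nf, length(header))
  if (nf > 0) {
    parts <- strsplit(body, ",", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc != length(header)))
      stop("inconsistent field counts in ", path)
    mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                  nf, length(header), byrow = TRUE)
  }
  pos <- array(NA_real_, c(nf, length(labels), 3))
  for (i in seq_along(labels))
    pos[, i, ] <- mat[, (3 * i - 2):(3 * i), drop = FALSE]
  mocap_sequence(pos, labels, fps)
}

write_mocap_trc <- function(seq, path) {
  nf <- n_frames(seq)
  nm <- n_markers(seq)
  mat <- flatten_positions(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PathFileType", "4", "(X/Y/Z)", basename(path),
                   sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(fmt_num(seq$fps), fmt_num(seq$fps), nf, nm, "mm",
                   fmt_num(seq$fps), 1, nf, sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(seq$labels, "", ""))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                                    rep(seq_len(nm), each = 3))),
                   collapse = "\t"), con)
  if (nf > 0) {
    tvec <- (seq_len(nf) - 1) / seq$fps
    body <- vapply(seq_len(nf), function(i)
      paste(c(i, fmt_num(tvec[i]), fmt_num(mat[i, ])), collapse = "\t"),
      character(1))
    writeLines(body, con)
  }
}

read_mocap_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L) stop("truncated TRC file: ", path)
  meta <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  fps <- as.numeric(meta[1])
  nm <- as.integer(meta[4])
  hdr <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- hdr[-(1:2)]
  labels <- labels[labels != ""]
  if (length(labels) != nm)
    stop("TRC header lists ", length(labels), " markers, expected ", nm)
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  nf <- length(body)
  pos <- array(NA_real_, c(nf, nm, 3))
  if (nf > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_len(nf)) {
      f <- parts[[i]]
      need <- 2 + 3 * nm
      if (length(f) < need) f <- c(f, rep("", need - length(f)))
      vals <- suppressWarnings(as.numeric(f[3:need]))
      pos[i, , ] <- matrix(vals, nm, 3, byrow = TRUE)
    }
  }
  mocap_sequence(pos, labels, fps)
}
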