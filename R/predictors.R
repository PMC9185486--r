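#' Moving median filter
#'
#' Element `i` is the median of the window of `window` samples centred
#' at `i`; near the edges the window shrinks symmetrically so the filter
#' stays centred and maps constants to themselves.
#'
#' @param x numeric vector.
#' @param window odd window length in samples.
#' @return filtered vector of the same length.
#' @export
moving_median <- function(x, window) {
  if (window %% 2 != 1 || window < 1) stop("`window` must be odd and >= 1")
  n <- length(x)
  if (n == 0L || window == 1L) return(x)
  out <- stats::runmed(x, min(window, 2 * ((n - 1) %/% 2) + 1),
                       endrule = "keep")
  h <- (window - 1) %/% 2
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n)))
  for (i in edge) {
    hh <- min(i - 1L, n - i)
    out[i] <- stats::median(x[(i - hh):(i + hh)])
  }
  as.numeric(out)
}

#' Savitzky-Golay low- and high-pass filtering
#'
#' The low-pass output at each sample is the value of the degree-`L`
#' polynomial fit by least squares to the window of `M` samples centred
#' there (asymmetric fits at the edges), so polynomials of degree at
#' most `L` are reproduced exactly.  The high-pass variant is the
#' complementary difference `x - low(x)`, hence `low + high` decompose
#' the signal exactly.
#'
#' @param x numeric vector.
#' @param L polynomial order (must satisfy `L < M`).
#' @param M odd window length.
#' @param mode `"low"` (smoothing) or `"high"` (residual).
#' @return filtered vector of the same length.
#' @export
savgol <- function(x, L = 5, M = 13, mode = c("low", "high")) {
  mode <- match.arg(mode)
  if (M %% 2 != 1 || M < 3) stop("`M` must be odd and >= 3")
  if (L >= M) stop("polynomial order `L` must be smaller than window `M`")
  if (length(x) < M) stop("signal shorter than the filter window")
  n <- length(x)
  h <- (M - 1L) %/% 2L
  Q <- savgol_basis(L, M)
  # interior: convolution with the centre row of the hat matrix
  w <- as.vector(Q %*% Q[h + 1L, ])
  low <- as.numeric(stats::filter(x, w, sides = 2))
  # edges: asymmetric fits from the hat rows of the boundary windows
  H <- tcrossprod(Q)
  low[seq_len(h)] <- (H %*% x[seq_len(M)])[seq_len(h)]
  low[seq.int(n - h + 1L, n)] <-
    (H %*% x[seq.int(n - M + 1L, n)])[seq.int(M - h + 1L, M)]
  switch(mode, low = low, high = x - low)
}

# orthonormal basis of degree-<=L polynomials sampled on the window,
# from a QR factorisation of the Vandermonde matrix on [-1, 1]; the
# orthogonalisation keeps high orders (e.g. L = 13 over 101 samples)
# numerically stable where the textbook normal equations collapse
savgol_basis <- function(L, M) {
  h <- (M - 1) / 2
  V <- outer(seq(-h, h) / h, 0:L, `^`)
  qr.Q(qr(V))
}

#' Laplace dispersion of a residual
#'
#' Prediction residuals are modelled as zero-mean Laplace (double
#' exponential).  The scale is tied to the residual standard deviation
#' `sigma_R` through the Laplace variance `2 b^2`, giving
#' `b = sigma_R / sqrt(2)`.
#'
#' @param residual numeric vector (NAs from missing prediction context
#'   are ignored).
#' @return list with elements `b` and `sigma_R` (both in mm).
#' @export
fit_laplace <- function(residual) {
  r <- residual[is.finite(residual)]
  if (length(r) < 2L) stop("need at least two finite residuals")
  sigma_R <- stats::sd(r)
  list(b = sigma_R / sqrt(2), sigma_R = sigma_R)
}

# centred moving average with symmetric edge shrink, O(n)
moving_average <- function(x, window) {
  n <- length(x)
  h <- window %/% 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# rows of the loose design: for each regressor marker, coordinates x,y,z
# at lags 0..k, raised to powers 1..L; first `lag_pad` frames lack
# context and come back as NA rows
loose_design <- function(seq, regressors, k, L) {
  n <- n_frames(seq)
  blocks <- list()
  for (r in regressors) {
    xyz <- marker_xyz(seq, r)
    for (p in seq_len(L)) {
      xp <- xyz^p
      for (lag in 0:k) {
        lagged <- if (lag == 0) xp else
          rbind(matrix(NA_real_, lag, 3), xp[seq_len(n - lag), , drop = FALSE])
        colnames(lagged) <- paste0(r, "_", c("x", "y", "z"),
                                   "_p", p, "_l", lag)
        blocks[[length(blocks) + 1L]] <- lagged
      }
    }
  }
  do.call(cbind, blocks)
}

#' Fit the loose polynomial predictor for one marker
#'
#' Ordinary least-squares regression of each coordinate of `marker` on
#' current and `k` past positions of its siblings and of the parent
#' group's representative, raised to powers `1..L`, plus an intercept.
#' The marker's own past and current positions are deliberately
#' excluded, so the prediction cannot follow an artifact on the marker
#' itself (a "loose" predictor).
#'
#' @param seq a [mocap_sequence].
#' @param hier a [body_hierarchy].
#' @param marker target marker name.
#' @param k number of past frames of each regressor (default 3).
#' @param L maximal power of each regressor (default 4).
#' @return a `predictor_model` with per-coordinate coefficients,
#'   fitted values, residual dispersion `sigma_R` and Laplace `b`.
#' @export
fit_loose_polynomial <- function(seq, hier, marker, k = 3, L = 4) {
  lr <- loose_regressors(seq, hier, marker)
  X <- cbind(intercept = 1, loose_design(seq, lr$regressors, k, L))
  Y <- marker_xyz(seq, marker)
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  if (sum(ok) <= ncol(X))
    stop("not enough frames (", sum(ok), ") for ", ncol(X), " coefficients")
  Xo <- X[ok, , drop = FALSE]
  qrX <- qr(Xo)
  if (qrX$rank < ncol(Xo)) {
    warning("rank-deficient loose design for ", marker,
            "; using pseudo-inverse solution")
    sv <- svd(Xo)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], Y[ok, , drop = FALSE]) / sv$d[pos])
  } else {
    beta <- qr.coef(qrX, Y[ok, , drop = FALSE])
  }
  beta[is.na(beta)] <- 0
  pred <- matrix(NA_real_, n_frames(seq), 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  pred[ok, ] <- Xo %*% beta
  res <- Y - pred
  lap <- fit_laplace(res)
  structure(list(kind = "poly_loose", marker = marker,
                 regressors = lr$regressors, parent_rep = lr$parent_rep,
                 k = k, L = L, coef = beta,
                 fitted = pred,
                 sigma_R = lap$sigma_R, b = lap$b,
                 sigma_R_coord = apply(res, 2, stats::sd, na.rm = TRUE)),
            class = "predictor_model")
}

#' Hyperparameters of the loose neural predictor
#'
#' @param k past frames of each regressor fed to the network (default 1).
#' @param L maximal power the regressor coordinates are raised to
#'   (default 2).
#' @param ma_window window of the moving average of the marker's own
#'   position, in samples; must be much longer than the artifacts to be
#'   detected so the network cannot follow them (default 200).
#' @param hidden1 sigmoid neurons in the first hidden layer (default 12).
#' @param hidden2_per_regressor sigmoid neurons in the second hidden
#'   layer per regressor marker (default 4).
#' @param P replication factor of the (x, y, z) output; the final
#'   prediction averages the `P` independently initialised replicas,
#'   emulating multi-start training (default 5).
#' @param seed RNG seed for weight initialisation.
#' @param max_epochs optimiser iteration cap.
#' @param train_stride training rows are subsampled at this stride (the
#'   100 Hz signal is heavily oversampled relative to the motion band,
#'   so a moderate stride changes the fit negligibly while keeping
#'   training time proportionate); predictions are still produced at
#'   every frame.
#' @return list of class `ffnn_params`.
#' @export
ffnn_params <- function(k = 1, L = 2, ma_window = 200, hidden1 = 12,
                        hidden2_per_regressor = 4, P = 5, seed = 1L,
                        max_epochs = 150L, train_stride = 4L) {
  stopifnot(k >= 0, L >= 1, P >= 1, ma_window > 1, hidden1 >= 1,
            hidden2_per_regressor >= 1, max_epochs >= 1, train_stride >= 1)
  structure(list(k = k, L = L, ma_window = ma_window, hidden1 = hidden1,
                 hidden2_per_regressor = hidden2_per_regressor, P = P,
                 seed = as.integer(seed), max_epochs = as.integer(max_epochs),
                 train_stride = as.integer(train_stride)),
            class = "ffnn_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ffnn_forward <- function(p, X) {
  A1 <- sigmoid(sweep(X %*% p$W1, 2, p$b1, `+`))
  A2 <- sigmoid(sweep(A1 %*% p$W2, 2, p$b2, `+`))
  Yh <- sweep(A2 %*% p$W3, 2, p$b3, `+`)
  list(A1 = A1, A2 = A2, Yh = Yh)
}

# standardisation helpers: constant columns get scale 1 and centre at
# their value, so they contribute zeros
std_fit <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(ctr = ctr, scl = scl)
}
std_apply <- function(M, s) sweep(sweep(M, 2, s$ctr, `-`), 2, s$scl, `/`)

#' Fit the loose feed-forward neural predictor for one marker
#'
#' A fully connected network with two sigmoid hidden layers (12 neurons,
#' then 4 per regressor marker) and a linear output of `3 * P` values:
#' `P` replicas of the (x, y, z) prediction whose weights are
#' independently initialised, so averaging them suppresses the
#' uncorrelated part of each replica's error while genuine deviations
#' of the marker from its neighbours survive in the residual.  Inputs
#' are the current and `k` past positions of the siblings and parent
#' representative raised to powers `1..L`, plus a long moving average of
#' the marker's own coordinates; the marker's own momentary position is
#' never an input.  Inputs and targets are z-scored internally and
#' training minimises mean squared error with a quasi-Newton
#' (limited-memory BFGS) optimiser from a seeded initialisation, so the
#' fit is reproducible.
#'
#' @inheritParams fit_loose_polynomial
#' @param params an [ffnn_params] list.
#' @param exclude optional logical per-frame vector; frames marked
#'   `TRUE` (e.g. spans flagged by earlier detection stages) are left
#'   out of the training rows and of the residual-dispersion estimate,
#'   so the network is fitted on frames believed clean.  Predictions
#'   are still produced for every frame with context.
#' @return a `predictor_model`; `fitted` holds the replica-averaged
#'   prediction at every frame with sufficient context.
#' @export
fit_loose_ffnn <- function(seq, hier, marker, params = ffnn_params(),
                           exclude = NULL) {
  lr <- loose_regressors(seq, hier, marker)
  Y <- marker_xyz(seq, marker)
  X <- loose_design(seq, lr$regressors, params$k, params$L)
  ma <- apply(Y, 2, moving_average, window = params$ma_window)
  colnames(ma) <- paste0("ma_", c("x", "y", "z"))
  X <- cbind(X, ma)
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  trainable <- ok
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == n_frames(seq))
    trainable <- trainable & !exclude
  }
  h1 <- params$hidden1
  h2 <- params$hidden2_per_regressor * length(lr$regressors)
  P <- params$P
  O <- 3L * P
  nfeat <- ncol(X)
  if (sum(ok) < 10 * (nfeat + h1 + h2))
    warning("few training frames relative to network size for ", marker)
  sx <- std_fit(X[trainable, , drop = FALSE])
  sy <- std_fit(Y[trainable, , drop = FALSE])
  tr <- which(trainable)[seq(1, sum(trainable), by = params$train_stride)]
  Xs <- std_apply(X[tr, , drop = FALSE], sx)
  Yr <- std_apply(Y[tr, , drop = FALSE], sy)[, rep(1:3, P), drop = FALSE]
  N <- nrow(Xs)
  sizes <- c(nfeat * h1, h1, h1 * h2, h2, h2 * O, O)
  idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  unpack <- function(w) list(
    W1 = matrix(w[idx[[1]]], nfeat, h1), b1 = w[idx[[2]]],
    W2 = matrix(w[idx[[3]]], h1, h2), b2 = w[idx[[4]]],
    W3 = matrix(w[idx[[5]]], h2, O), b3 = w[idx[[6]]])
  # optim evaluates fn and gr back to back at the same point; cache the
  # forward pass
  last_w <- NULL
  last_f <- NULL
  fwd_at <- function(w, p) {
    if (is.null(last_w) || !identical(w, last_w)) {
      last_w <<- w
      last_f <<- ffnn_forward(p, Xs)
    }
    last_f
  }
  fn <- function(w) {
    f <- fwd_at(w, unpack(w))
    mean((f$Yh - Yr)^2)
  }
  gr <- function(w) {
    p <- unpack(w)
    f <- fwd_at(w, p)
    dY <- 2 * (f$Yh - Yr) / (N * O)
    dA2 <- (dY %*% t(p$W3)) * f$A2 * (1 - f$A2)
    dA1 <- (dA2 %*% t(p$W2)) * f$A1 * (1 - f$A1)
    c(crossprod(Xs, dA1), colSums(dA1),
      crossprod(f$A1, dA2), colSums(dA2),
      crossprod(f$A2, dY), colSums(dY))
  }
  glorot <- function(fi, fo) stats::runif(fi * fo, -1, 1) * sqrt(6 / (fi + fo))
  w0 <- with_local_seed(params$seed, {
    c(glorot(nfeat, h1), rep(0, h1),
      glorot(h1, h2), rep(0, h2),
      glorot(h2, O), rep(0, O))
  })
  opt <- stats::optim(w0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = params$max_epochs))
  if (opt$convergence != 0 && opt$convergence != 1)
    warning("FFNN optimiser reported convergence code ", opt$convergence,
            " for ", marker, "; returning best weights found")
  weights <- unpack(opt$par)
  Yh <- ffnn_forward(weights, std_apply(X[ok, , drop = FALSE], sx))$Yh
  # final prediction: mean of the P (x, y, z) replicas, de-standardised
  predn <- vapply(1:3, function(c3) rowMeans(Yh[, seq(c3, O, by = 3),
                                                drop = FALSE]),
                  numeric(sum(ok)))
  predn <- sweep(sweep(predn, 2, sy$scl, `*`), 2, sy$ctr, `+`)
  pred <- matrix(NA_real_, n_frames(seq), 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  pred[ok, ] <- predn
  res <- Y - pred
  res_clean <- res[trainable, , drop = FALSE]
  lap <- fit_laplace(res_clean)
  structure(list(kind = "ffnn_loose", marker = marker,
                 regressors = lr$regressors, parent_rep = lr$parent_rep,
                 k = params$k, L = params$L, params = params,
                 weights = weights, x_std = sx, y_std = sy,
                 fitted = pred, loss = opt$value,
                 sigma_R = lap$sigma_R, b = lap$b,
                 sigma_R_coord = apply(res_clean, 2, stats::sd,
                                       na.rm = TRUE),
                 # robust (MAD-based) scale of the same residuals: the
                 # normal variability, insensitive to artifacts still
                 # present in the fitting window
                 sigma_robust_coord = apply(res_clean, 2, stats::mad,
                                            na.rm = TRUE)),
            class = "predictor_model")
}

# run `expr` under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("predictor_model (%s) for marker %s\n", x$kind, x$marker))
  cat(sprintf("  regressors: %s\n", paste(x$regressors, collapse = ", ")))
  cat(sprintf("  sigma_R = %.4g mm, Laplace b = %.4g mm\n", x$sigma_R, x$b))
  invisible(x)
}

#' Predict a marker's positions from a fitted loose model
#'
#' @param model a `predictor_model` from [fit_loose_polynomial] or
#'   [fit_loose_ffnn].
#' @param seq a [mocap_sequence] containing the model's marker and
#'   regressors (defaults to reusing the fit-time values when `NULL`).
#' @return numeric `frames x 3` matrix; frames lacking full regressor
#'   context are `NA`, never fabricated.
#' @export
predict_positions <- function(model, seq = NULL) {
  if (is.null(seq)) return(model$fitted)
  if (!model$marker %in% seq$labels)
    stop("marker ", model$marker, " absent from sequence")
  if (model$kind == "poly_loose") {
    X <- cbind(intercept = 1, loose_design(seq, model$regressors,
                                           model$k, model$L))
    ok <- stats::complete.cases(X)
    pred <- matrix(NA_real_, n_frames(seq), 3,
                   dimnames = list(NULL, c("x", "y", "z")))
    pred[ok, ] <- X[ok, , drop = FALSE] %*% model$coef
    return(pred)
  }
  params <- model$params
  Y <- marker_xyz(seq, model$marker)
  X <- loose_design(seq, model$regressors, params$k, params$L)
  ma <- apply(Y, 2, moving_average, window = params$ma_window)
  X <- cbind(X, ma)
  ok <- stats::complete.cases(X)
  Yh <- ffnn_forward(model$weights,
                     std_apply(X[ok, , drop = FALSE], model$x_std))$Yh
  O <- 3L * params$P
  predn <- vapply(1:3, function(c3) rowMeans(Yh[, seq(c3, O, by = 3),
                                                drop = FALSE]),
                  numeric(sum(ok)))
  predn <- sweep(sweep(predn, 2, model$y_std$scl, `*`), 2,
                 model$y_std$ctr, `+`)
  pred <- matrix(NA_real_, n_frames(seq), 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  pred[ok, ] <- predn
  pred
}

#' Residual of a loose prediction
#'
#' The residual is observation minus prediction, per coordinate; it is
#' the signal the slow-change detector thresholds.  Frames without full
#' regressor context are `NA`.
#'
#' @param model a `predictor_model`.
#' @param seq the [mocap_sequence] to score (required; the observation
#'   is needed alongside the prediction).
#' @return numeric `frames x 3` matrix of residuals in mm.
#' @export
predict_residual <- function(model, seq = NULL) {
  pred <- predict_positions(model, seq)
  obs <- if (is.null(seq)) NULL else marker_xyz(seq, model$marker)
  if (is.null(obs)) stop("`seq` is required to compute residuals")
  obs - pred
}
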