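# The two network gap fillers: a single-hidden-layer feed-forward ANN
# (5 sigmoidal hidden units, linear output; fitted via nnet with seeded
# restarts selected on an internal validation split) and a radial-basis-
# function network (Gaussian bases at k-means centers, default 181, linear
# output weights by ridge-regularized least squares). Targets are
# standardized internally; both fits are reproducible by seed.

#' Fit the single-hidden-layer neural network
#'
#' @param x Numeric matrix of normalized drivers.
#' @param y Numeric response (flux); standardized internally.
#' @param size Hidden units (default 5).
#' @param decay Weight decay used during training.
#' @param maxit Optimizer iteration cap.
#' @param restarts Seeded random restarts; the net with the lowest MSE on an
#'   internal validation split is kept (guards against bad initializations
#'   and overfitting).
#' @param val_fraction Share of the training rows held out for restart
#'   selection.
#' @param seed Integer seed; identical seeds give identical weights.
#' @return A `net_spec` (kind `"ann"`).
#' @export
fit_ann <- function(x, y, size = 5, decay = 1e-3, maxit = 500,
                    restarts = 3, val_fraction = 0.2, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (is.na(y_sd) || y_sd == 0) {
    return(net_constant("ann", y_mean))
  }
  ys <- (y - y_mean) / y_sd
  set.seed(substream_seed(seed, 21L))
  n_val <- max(1L, round(val_fraction * n))
  val <- sample.int(n, n_val)
  fit_idx <- setdiff(seq_len(n), val)
  best <- NULL
  best_mse <- Inf
  for (r in seq_len(restarts)) {
    net <- nnet::nnet(x[fit_idx, , drop = FALSE], ys[fit_idx],
      size = size, linout = TRUE, decay = decay, maxit = maxit,
      trace = FALSE, MaxNWts = 5000
    )
    mse <- mean((predict(net, x[val, , drop = FALSE]) - ys[val])^2)
    if (mse < best_mse) {
      best <- net
      best_mse <- mse
    }
  }
  structure(
    list(
      kind = "ann", fit = best, y_mean = y_mean, y_sd = y_sd,
      constant = NULL, val_mse = best_mse, size = size, n = n
    ),
    class = "net_spec"
  )
}

#' Fit the radial-basis-function network
#'
#' Gaussian basis centers are placed by k-means on the driver space
#' (`n_centers`, capped at the number of distinct rows); each center's width
#' is its distance to the nearest other center (floored at a small constant);
#' output weights solve a ridge-regularized least-squares problem.
#'
#' @inheritParams fit_ann
#' @param n_centers Hidden basis count (default 181).
#' @param ridge Ridge penalty on the output weights.
#' @return A `net_spec` (kind `"rbf"`).
#' @export
fit_rbf <- function(x, y, n_centers = 181, ridge = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (is.na(y_sd) || y_sd == 0) {
    return(net_constant("rbf", y_mean))
  }
  ys <- (y - y_mean) / y_sd
  set.seed(substream_seed(seed, 22L))
  k <- min(n_centers, nrow(unique(x)))
  centers <- if (k < 2) {
    matrix(colMeans(x), 1)
  } else {
    kmeans(x, centers = k, iter.max = 100, nstart = 1)$centers
  }
  widths <- center_widths(centers)
  phi <- rbf_design(x, centers, widths)
  m <- ncol(phi)
  w <- solve(
    crossprod(phi) + ridge * diag(m),
    crossprod(phi, ys)
  )
  structure(
    list(
      kind = "rbf", centers = centers, widths = widths, w = as.numeric(w),
      y_mean = y_mean, y_sd = y_sd, constant = NULL, n = n
    ),
    class = "net_spec"
  )
}

center_widths <- function(centers) {
  k <- nrow(centers)
  if (k == 1) {
    return(1)
  }
  dd <- as.matrix(stats::dist(centers))
  diag(dd) <- Inf
  pmax(apply(dd, 1, min), 1e-6)
}

rbf_design <- function(x, centers, widths) {
  k <- nrow(centers)
  phi <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    d2 <- rowSums(sweep(x, 2, centers[j, ])^2)
    phi[, j] <- exp(-0.5 * d2 / widths[j]^2)
  }
  cbind(1, phi)
}

net_constant <- function(kind, value) {
  structure(
    list(
      kind = kind, fit = NULL, y_mean = value, y_sd = 0, constant = value
    ),
    class = "net_spec"
  )
}

#' Predict from a fitted network
#'
#' @param spec A `net_spec` from [fit_ann()] or [fit_rbf()].
#' @param xnew Driver matrix (same columns as training).
#' @return Numeric predictions in flux units.
#' @export
predict_net <- function(spec, xnew) {
  xnew <- as.matrix(xnew)
  if (!is.null(spec$constant)) {
    return(rep(spec$constant, nrow(xnew)))
  }
  ys <- if (spec$kind == "ann") {
    as.numeric(predict(spec$fit, xnew))
  } else {
    as.numeric(rbf_design(xnew, spec$centers, spec$widths) %*% spec$w)
  }
  ys * spec$y_sd + spec$y_mean
}

#' @export
print.net_spec <- function(x, ...) {
  cat(sprintf("<net_spec: %s>\n", x$kind))
  if (!is.null(x$constant)) {
    cat(sprintf("  constant prediction %.4g (zero-variance target)\n", x$constant))
  } else if (x$kind == "ann") {
    cat(sprintf("  %d hidden units, n = %d, val mse = %.4g\n", x$size, x$n, x$val_mse))
  } else {
    cat(sprintf("  %d centers, n = %d\n", nrow(x$centers), x$n))
  }
  invisible(x)
}
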