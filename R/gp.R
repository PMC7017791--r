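# Exact Gaussian-process regression with a squared-exponential kernel and
# automatic relevance determination (one length scale per driver) plus a
# nugget. Targets are standardized internally so the zero mean function is
# appropriate; hyperparameters maximize the log marginal likelihood by
# multi-start L-BFGS-B with analytic gradients.

#' Fit a GP regression with SE-ARD kernel
#'
#' Kernel: `k(x, x') = sf2 * exp(-0.5 * sum_d (x_d - x'_d)^2 / ls_d^2)` plus
#' nugget variance `sn2` on the diagonal. Hyperparameters (`sf2`, per-input
#' length scales `ls_d`, `sn2`) are optimized on the log scale against the
#' exact log marginal likelihood. For training sets larger than
#' `subset_size`, a seeded random subset of that size is used (subset-of-data
#' approximation); set `subset_size = Inf` for the exact fit at any size.
#'
#' @param x Numeric matrix of normalized drivers (rows = records).
#' @param y Numeric response (flux); standardized internally.
#' @param subset_size Training-subset cap (default 800).
#' @param restarts Extra random restarts of the optimizer (default 2).
#' @param maxit L-BFGS-B iteration cap per start.
#' @param seed Integer seed (subset choice and restart jitter).
#' @param jitter Diagonal jitter added for numerical positive-definiteness.
#' @return A `gp_spec` with hyperparameters and the cached training solve.
#' @export
fit_gp <- function(x, y, subset_size = 800, restarts = 2, maxit = 60,
                   seed = 1L, jitter = 1e-8) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  set.seed(substream_seed(seed, 11L))
  if (nrow(x) > subset_size) {
    keep <- sort(sample.int(nrow(x), subset_size))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(x)
  d <- ncol(x)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  # theta = c(log sf2, log ls_1..d, log sn2); optim asks for the value and
  # the gradient in separate calls, so cache the last evaluation
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- gp_nll(theta, x, ys, jitter, grad = TRUE)
      cache$key <- key
    }
    cache$res
  }

  starts <- list(c(0, rep(0, d), log(0.1)))
  for (r in seq_len(restarts)) {
    starts[[r + 1]] <- starts[[1]] + rnorm(d + 2, 0, 0.7)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, function(th) eval_cached(th)$value,
        gr = function(th) eval_cached(th)$grad,
        method = "L-BFGS-B", lower = -8, upper = 8,
        control = list(maxit = maxit)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("GP hyperparameter optimization failed on all starts.", call. = FALSE)
  }
  theta <- best$par
  kk <- gp_kernel(x, x, theta)
  diag(kk) <- diag(kk) + exp(theta[d + 2]) + jitter
  ch <- chol_psd(kk, jitter)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(
    list(
      x = x, chol = ch, alpha = alpha,
      sf2 = exp(theta[1]), length_scales = exp(theta[2:(d + 1)]),
      sn2 = exp(theta[d + 2]),
      y_mean = y_mean, y_sd = y_sd, theta = theta,
      log_marginal = -best$value, n = n
    ),
    class = "gp_spec"
  )
}

# negative log marginal likelihood (and gradient) in standardized units
gp_nll <- function(theta, x, ys, jitter, grad = FALSE) {
  n <- nrow(x)
  d <- ncol(x)
  sf2 <- exp(theta[1])
  ls2 <- exp(2 * theta[2:(d + 1)])
  sn2 <- exp(theta[d + 2])
  sq <- matrix(0, n, n)
  for (j in seq_len(d)) {
    sq <- sq + outer(x[, j], x[, j], "-")^2 / ls2[j]
  }
  kse <- sf2 * exp(-0.5 * sq)
  kk <- kse
  diag(kk) <- diag(kk) + sn2 + jitter
  ch <- tryCatch(chol(kk), error = function(e) NULL)
  if (is.null(ch)) {
    return(list(value = 1e10, grad = rep(0, d + 2)))
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  value <- 0.5 * sum(ys * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  if (!grad) {
    return(list(value = value))
  }
  kinv <- chol2inv(ch)
  w <- kinv - tcrossprod(alpha) # d(nll)/dK = 0.5 * W
  g <- numeric(d + 2)
  g[1] <- 0.5 * sum(w * kse) # d/d log sf2
  for (j in seq_len(d)) {
    dk <- kse * (outer(x[, j], x[, j], "-")^2 / ls2[j]) # d/d log ls_j
    g[j + 1] <- 0.5 * sum(w * dk)
  }
  g[d + 2] <- 0.5 * sum(diag(w)) * sn2
  list(value = value, grad = g)
}

gp_kernel <- function(xa, xb, theta) {
  d <- ncol(xa)
  sf2 <- exp(theta[1])
  ls2 <- exp(2 * theta[2:(d + 1)])
  sq <- matrix(0, nrow(xa), nrow(xb))
  for (j in seq_len(d)) {
    sq <- sq + outer(xa[, j], xb[, j], "-")^2 / ls2[j]
  }
  sf2 * exp(-0.5 * sq)
}

chol_psd <- function(kk, jitter) {
  for (i in 0:6) {
    ch <- tryCatch(chol(kk), error = function(e) NULL)
    if (!is.null(ch)) {
      return(ch)
    }
    diag(kk) <- diag(kk) + jitter * 10^i
  }
  stop("kernel matrix not positive definite after jitter escalation.",
    call. = FALSE
  )
}

#' Posterior mean and variance of a fitted GP
#'
#' Exact GP posterior under the SE-ARD kernel, de-standardized to flux units.
#' `var` is the posterior variance of the latent function (zero at a training
#' input as the nugget vanishes, growing with distance from the data);
#' `var_obs` adds the nugget, i.e. the predictive variance of a new noisy
#' observation.
#'
#' @param spec A `gp_spec` from [fit_gp()].
#' @param xnew Matrix of driver rows to predict (same columns as training).
#' @param block Rows per prediction block (memory control).
#' @return A tibble with `mean`, `var`, `var_obs`.
#' @export
predict_gp <- function(spec, xnew, block = 2000L) {
  xnew <- as.matrix(xnew)
  if (ncol(xnew) != ncol(spec$x)) {
    stop("driver dimension mismatch: model has ", ncol(spec$x),
      " inputs, got ", ncol(xnew),
      call. = FALSE
    )
  }
  n <- nrow(xnew)
  mean_out <- numeric(n)
  var_out <- numeric(n)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1, n)
    ks <- gp_kernel(xnew[s:e, , drop = FALSE], spec$x, spec$theta)
    mean_out[s:e] <- as.numeric(ks %*% spec$alpha)
    v <- forwardsolve(t(spec$chol), t(ks))
    var_out[s:e] <- pmax(spec$sf2 - colSums(v^2), 0)
  }
  tibble::tibble(
    mean = mean_out * spec$y_sd + spec$y_mean,
    var = var_out * spec$y_sd^2,
    var_obs = (var_out + spec$sn2) * spec$y_sd^2
  )
}

#' @export
print.gp_spec <- function(x, ...) {
  cat("<gp_spec>\n")
  cat(sprintf(
    "  n = %d, D = %d; sf2 = %.3g, sn2 = %.3g, log marginal = %.1f\n",
    x$n, ncol(x$x), x$sf2, x$sn2, x$log_marginal
  ))
  cat("  length scales:", paste(signif(x$length_scales, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
glance.gp_spec <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, sf2 = x$sf2, sn2 = x$sn2, log_marginal = x$log_marginal
  )
}
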