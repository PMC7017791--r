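# Varying-intercept hierarchical linear model with a ridge prior on the
# driver coefficients, fitted by empirical-Bayes conjugate-normal inference:
# y_i = gamma + a_{g(i)} + x_i' beta + e_i, with a_g ~ N(0, sigma_a^2),
# beta ~ N(0, sigma_b^2 I), e ~ N(0, sigma_y^2). Variance components maximize
# the marginal likelihood; intercepts are partially pooled toward the
# group-level mean gamma. In the conjugate case the posterior means equal the
# full Bayes answer, deterministically and in closed form.

#' Fit the varying-intercept hierarchical model
#'
#' @param x Numeric driver matrix (rows = records).
#' @param y Numeric response (flux).
#' @param group Integer group index per row, 1..`n_groups` (time of day by
#'   default in [fill_gaps()], 48 half-hour groups).
#' @param n_groups Total number of groups (default `max(group)`, at least 48
#'   when the grouping is time of day).
#' @param rho_alpha,rho_beta Optional fixed variance ratios
#'   `sigma_a^2 / sigma_y^2` and `sigma_b^2 / sigma_y^2`; `NULL` (default)
#'   estimates them by marginal-likelihood maximization. Large fixed
#'   `rho_beta` recovers unpenalized least squares; `rho_beta -> 0` shrinks
#'   `beta` to zero.
#' @return An `hlm_spec` with `gamma` (group-level mean), `a` (posterior
#'   intercept deviations), `alpha = gamma + a`, `beta`, variance components,
#'   posterior intercept variances, and the maximized log marginal
#'   likelihood.
#' @export
fit_hlm <- function(x, y, group, n_groups = NULL,
                    rho_alpha = NULL, rho_beta = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(nrow(x) == n, length(group) == n)
  n_groups <- n_groups %||% max(group)
  d <- ncol(x)
  zu <- matrix(0, n, n_groups)
  zu[cbind(seq_len(n), group)] <- 1
  u <- cbind(zu, x)
  m <- n_groups + d

  empty <- setdiff(seq_len(n_groups), unique(group))
  if (length(empty)) {
    message(
      length(empty), " empty group(s): ",
      paste(utils::head(empty, 8), collapse = ", "),
      if (length(empty) > 8) ", ..." else "",
      "; their intercepts fall back to the group-level mean."
    )
  }

  utu <- crossprod(u)
  u1 <- colSums(u)
  uy <- as.numeric(crossprod(u, y))
  yy <- sum(y^2)
  sy <- sum(y)

  profile <- function(log_rho) {
    rho <- exp(log_rho)
    dvec <- c(rep(rho[1], n_groups), rep(rho[2], d))
    mm <- utu + diag(1 / dvec, m)
    ch <- tryCatch(chol(mm), error = function(e) NULL)
    if (is.null(ch)) {
      return(list(nll = 1e10))
    }
    z1 <- backsolve(ch, forwardsolve(t(ch), u1))
    zy <- backsolve(ch, forwardsolve(t(ch), uy))
    v11 <- n - sum(u1 * z1)
    v1y <- sy - sum(u1 * zy)
    vyy <- yy - sum(uy * zy)
    gamma <- v1y / v11
    q <- vyy - v1y^2 / v11
    sigma_y2 <- q / n
    logdet_v <- 2 * sum(log(diag(ch))) + sum(log(dvec))
    nll <- 0.5 * (n * log(2 * pi * sigma_y2) + logdet_v + n)
    list(
      nll = nll, gamma = gamma, sigma_y2 = sigma_y2, chol = ch, dvec = dvec
    )
  }

  free <- c(is.null(rho_alpha), is.null(rho_beta))
  fixed <- log(c(rho_alpha %||% 1, rho_beta %||% 1))
  obj <- function(par) {
    lr <- fixed
    lr[free] <- par
    profile(lr)$nll
  }
  if (any(free)) {
    best <- NULL
    for (start in list(rep(0, sum(free)), rep(3, sum(free)))) {
      fit <- optim(start, obj,
        method = if (sum(free) == 1) "Brent" else "Nelder-Mead",
        lower = if (sum(free) == 1) -12 else -Inf,
        upper = if (sum(free) == 1) 12 else Inf,
        control = list(maxit = 400)
      )
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    log_rho <- fixed
    log_rho[free] <- best$par
  } else {
    log_rho <- fixed
  }
  sol <- profile(log_rho)
  coefs <- backsolve(
    sol$chol,
    forwardsolve(t(sol$chol), uy - u1 * sol$gamma)
  )
  post_var <- sol$sigma_y2 * diag(chol2inv(sol$chol))
  a <- coefs[seq_len(n_groups)]
  beta <- coefs[n_groups + seq_len(d)]
  names(beta) <- colnames(x) %||% paste0("x", seq_len(d))
  rho <- exp(log_rho)
  structure(
    list(
      gamma = sol$gamma, a = a, alpha = sol$gamma + a, beta = beta,
      sigma_y2 = sol$sigma_y2,
      sigma_a2 = rho[1] * sol$sigma_y2,
      sigma_b2 = rho[2] * sol$sigma_y2,
      alpha_var = post_var[seq_len(n_groups)],
      beta_var = post_var[n_groups + seq_len(d)],
      n_groups = n_groups, n = n,
      log_marginal = -sol$nll, empty_groups = empty
    ),
    class = "hlm_spec"
  )
}

#' Predict from a fitted hierarchical model
#'
#' `prediction = gamma + a_{g(row)} + x' beta`; rows in groups unseen at fit
#' time use the group-level mean (`a = 0`).
#'
#' @param spec An `hlm_spec` from [fit_hlm()].
#' @param x Driver matrix (same columns as training).
#' @param group Integer group per row.
#' @return Numeric predictions.
#' @export
predict_hlm <- function(spec, x, group) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(spec$beta))
  a <- spec$a[pmin(group, spec$n_groups)]
  a[is.na(a)] <- 0
  spec$gamma + a + as.numeric(x %*% spec$beta)
}

#' @export
print.hlm_spec <- function(x, ...) {
  cat("<hlm_spec>\n")
  cat(sprintf(
    "  %d groups, %d drivers, n = %d; sigma_y2 = %.3g, sigma_a2 = %.3g, sigma_b2 = %.3g\n",
    x$n_groups, length(x$beta), x$n, x$sigma_y2, x$sigma_a2, x$sigma_b2
  ))
  invisible(x)
}

#' @export
tidy.hlm_spec <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("alpha_", seq_len(x$n_groups)), names(x$beta)),
    estimate = c(x$alpha, x$beta),
    std.error = sqrt(c(x$alpha_var, x$beta_var))
  )
}

#' @export
glance.hlm_spec <- function(x, ...) {
  tibble::tibble(
    sigma_y2 = x$sigma_y2, sigma_a2 = x$sigma_a2, sigma_b2 = x$sigma_b2,
    log_marginal = x$log_marginal, nobs = x$n
  )
}
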