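# Gap filling of the quality-controlled flux series by five methods (MDS, GP,
# HLM, ANN, RBF) under a common 80/20 train/test protocol with R2/RMSE/BE
# evaluation.

#' Random train/test split of the valid records
#'
#' @param idx Integer indices (or anything subsettable) of valid records.
#' @param fraction Training share in (0, 1); training size is
#'   `ceiling(fraction * n)`.
#' @param seed Integer seed making the partition reproducible.
#' @return A list with integer vectors `train` and `test` partitioning `idx`.
#' @export
split_train_test <- function(idx, fraction = 0.8, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("`fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  n <- length(idx)
  if (n < 10) stop("need at least 10 valid records to split.", call. = FALSE)
  set.seed(as.integer(seed))
  n_train <- ceiling(fraction * n)
  take <- sample.int(n, n_train)
  list(train = sort(idx[take]), test = sort(idx[-take]))
}

#' Prediction-skill metrics
#'
#' `r2 = 1 - SS_res / SS_tot`, `rmse = sqrt(mean((pred - obs)^2))`, and bias
#' error `be = mean(pred - obs)` (positive = overestimate).
#'
#' @param pred,obs Paired numeric vectors; pairs with `NA` are dropped.
#' @return A one-row tibble with `r2`, `rmse`, `be`, `n`.
#' @export
evaluate_fill <- function(pred, obs) {
  keep <- complete.cases(pred, obs)
  pred <- pred[keep]
  obs <- obs[keep]
  if (length(obs) < 2) stop("need at least 2 paired values.", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    stop("R2 undefined: observations have zero variance.", call. = FALSE)
  }
  tibble::tibble(
    r2 = 1 - sum((pred - obs)^2) / ss_tot,
    rmse = sqrt(mean((pred - obs)^2)),
    be = mean(pred - obs),
    n = length(obs)
  )
}

# ---- marginal distribution sampling -----------------------------------------

#' Marginal-distribution-sampling configuration
#'
#' Similarity tolerances and the window schedule of the MDS look-up. A gap is
#' filled by the mean of valid fluxes measured under similar meteorology
#' (incident radiation, air temperature, VPD all within tolerance) inside the
#' smallest time window yielding at least `min_matches` donors; when no
#' meteorological match exists the mean diurnal course (same time of day
#' within `hour_tol` hours) over expanding windows is used.
#'
#' @param tol_rd Radiation tolerance, W m^-2 (default 50).
#' @param tol_t_air Air-temperature tolerance, degC (default 2.5).
#' @param tol_vpd VPD tolerance, hPa (default 5).
#' @param meteo_windows Half-window widths in days for the similarity search.
#' @param mdc_windows Half-window widths in days for the diurnal-course
#'   fallback.
#' @param min_matches Minimum number of donors (default 2).
#' @param hour_tol Fallback time-of-day tolerance in hours (default 1).
#' @return An `mds_config` list.
#' @export
mds_config <- function(tol_rd = 50, tol_t_air = 2.5, tol_vpd = 5,
                       meteo_windows = c(7, 14),
                       mdc_windows = c(7, 14, 28, 56, 112, 183),
                       min_matches = 2, hour_tol = 1) {
  stopifnot(
    tol_rd > 0, tol_t_air > 0, tol_vpd > 0,
    length(meteo_windows) > 0, !is.unsorted(meteo_windows),
    length(mdc_windows) > 0, !is.unsorted(mdc_windows),
    min_matches >= 1
  )
  structure(
    list(
      tol_rd = tol_rd, tol_t_air = tol_t_air, tol_vpd = tol_vpd,
      meteo_windows = meteo_windows, mdc_windows = mdc_windows,
      min_matches = min_matches, hour_tol = hour_tol
    ),
    class = "mds_config"
  )
}

#' Fill target rows by marginal distribution sampling
#'
#' Deterministic look-up-table gap filler: see [mds_config()] for the search
#' scheme. Rows never matched even by the largest fallback window stay `NA`
#' and are listed in the `unfilled` attribute.
#'
#' @param table A time-ordered, uniformly spaced flux table with `rd`,
#'   `t_air`, `vpd` present on target rows.
#' @param targets Integer row indices to predict.
#' @param donors Integer row indices usable as donors (must have valid flux).
#' @param cfg An [mds_config()].
#' @return Numeric vector of predictions aligned with `targets`, with
#'   attributes `window_used` (days; `NA` for fallback-filled rows times -1)
#'   and `unfilled` (target indices left `NA`).
#' @export
fit_predict_mds <- function(table, targets, donors, cfg = mds_config()) {
  f <- table$f_c
  rd <- table$rd
  ta <- table$t_air
  vpd <- table$vpd
  slot <- floor(decimal_hour(table$timestamp) * 2) %% 48
  donors <- donors[!is.na(f[donors])]
  don_sorted <- sort(donors)
  pred <- rep(NA_real_, length(targets))
  window_used <- rep(NA_real_, length(targets))
  slot_tol <- round(cfg$hour_tol * 2)
  for (k in seq_along(targets)) {
    t <- targets[k]
    done <- FALSE
    for (w in cfg$meteo_windows) {
      cand <- donors_in_window(don_sorted, t, w * 48L)
      if (length(cand) < cfg$min_matches) next
      ok <- abs(rd[cand] - rd[t]) <= cfg$tol_rd &
        abs(ta[cand] - ta[t]) <= cfg$tol_t_air &
        abs(vpd[cand] - vpd[t]) <= cfg$tol_vpd
      if (sum(ok) >= cfg$min_matches) {
        pred[k] <- mean(f[cand[ok]])
        window_used[k] <- w
        done <- TRUE
        break
      }
    }
    if (done) next
    for (w in cfg$mdc_windows) {
      cand <- donors_in_window(don_sorted, t, w * 48L)
      if (!length(cand)) next
      ds <- abs(slot[cand] - slot[t])
      ok <- pmin(ds, 48 - ds) <= slot_tol
      if (sum(ok) >= cfg$min_matches) {
        pred[k] <- mean(f[cand[ok]])
        window_used[k] <- -w
        break
      }
    }
  }
  attr(pred, "window_used") <- window_used
  attr(pred, "unfilled") <- targets[is.na(pred)]
  pred
}

# donors (sorted row indices) within +/- half_window slots of row t
donors_in_window <- function(don_sorted, t, half_window) {
  lo <- findInterval(t - half_window - 0.5, don_sorted) + 1L
  hi <- findInterval(t + half_window + 0.5, don_sorted)
  if (hi < lo) integer(0) else don_sorted[lo:hi]
}

# ---- orchestrator ------------------------------------------------------------

#' Gap-fill a quality-controlled flux series by one method
#'
#' Runs the full protocol for one method: random 80/20 split of the valid
#' records, model training (or MDS look-up) on the training set, R2/RMSE/BE
#' on both sets, and prediction of every row. The filled series keeps
#' observed flux bit-exactly where valid and uses model predictions
#' elsewhere.
#'
#' @param table A quality-controlled, u*-screened flux table with driver
#'   columns.
#' @param method One of `"mds"`, `"gp"`, `"hlm"`, `"ann"`, `"rbf"`.
#' @param seed Integer seed controlling the split and any stochastic
#'   training.
#' @param train_fraction Training share of the valid records.
#' @param config Method configuration: an [mds_config()] for MDS, or a list
#'   of arguments forwarded to [fit_gp()], [fit_hlm()], [fit_ann()],
#'   [fit_rbf()].
#' @return A `fill_result`: `method`, `data` (tibble with `timestamp`,
#'   `observed`, `prediction`, `filled`, `source`), `metrics` (train/test
#'   rows), the fitted `model`, and `unfilled` indices (MDS only).
#' @export
fill_gaps <- function(table, method = c("mds", "gp", "hlm", "ann", "rbf"),
                      seed = 1L, train_fraction = 0.8, config = NULL) {
  method <- match.arg(method)
  table <- tibble::as_tibble(table)
  valid <- which(!is.na(table$f_c))
  parts <- split_train_test(valid, train_fraction, seed)
  gaps <- which(is.na(table$f_c))
  n <- nrow(table)

  if (method == "mds") {
    cfg <- config %||% mds_config()
    pred <- rep(NA_real_, n)
    pred[parts$train] <- fit_predict_mds(table, parts$train, parts$train, cfg)
    pred[parts$test] <- fit_predict_mds(table, parts$test, parts$train, cfg)
    gap_pred <- fit_predict_mds(table, gaps, valid, cfg)
    pred[gaps] <- gap_pred
    model <- cfg
    unfilled <- attr(gap_pred, "unfilled")
  } else {
    x <- driver_design_matrix(table[parts$train, ])
    scaler <- attr(x, "scaler")
    y <- table$f_c[parts$train]
    model <- switch(method,
      gp = rlang::exec(fit_gp, x, y, seed = seed, !!!(config %||% list())),
      hlm = rlang::exec(fit_hlm, x, y,
        group = tod_group(table$timestamp[parts$train]),
        !!!(config %||% list())
      ),
      ann = rlang::exec(fit_ann, x, y, seed = seed, !!!(config %||% list())),
      rbf = rlang::exec(fit_rbf, x, y, seed = seed, !!!(config %||% list()))
    )
    x_all <- driver_design_matrix(table, scaler = scaler)
    pred <- switch(method,
      gp = predict_gp(model, x_all)$mean,
      hlm = predict_hlm(model, x_all, group = tod_group(table$timestamp)),
      ann = predict_net(model, x_all),
      rbf = predict_net(model, x_all)
    )
    unfilled <- integer(0)
  }

  metrics <- dplyr::bind_rows(
    dplyr::mutate(
      evaluate_fill(pred[parts$train], table$f_c[parts$train]),
      set = "train", .before = 1
    ),
    dplyr::mutate(
      evaluate_fill(pred[parts$test], table$f_c[parts$test]),
      set = "test", .before = 1
    )
  )
  filled <- ifelse(is.na(table$f_c), pred, table$f_c)
  structure(
    list(
      method = method,
      data = tibble::tibble(
        timestamp = table$timestamp,
        observed = table$f_c,
        prediction = pred,
        filled = filled,
        source = ifelse(is.na(table$f_c), "filled", "observed")
      ),
      metrics = metrics,
      split = parts,
      model = model,
      unfilled = unfilled,
      seed = as.integer(seed)
    ),
    class = "fill_result"
  )
}

# time-of-day group 1..48 for the hierarchical model
tod_group <- function(ts) (floor(decimal_hour(ts) * 2) %% 48) + 1L

#' @export
print.fill_result <- function(x, ...) {
  cat(sprintf("<fill_result: %s>\n", x$method))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %-5s r2 = %.3f, rmse = %.3f, be = %+.3f (n = %d)\n",
      m$set[i], m$r2[i], m$rmse[i], m$be[i], m$n[i]
    ))
  }
  cat(sprintf(
    "  %d of %d rows filled%s\n",
    sum(x$data$source == "filled"), nrow(x$data),
    if (length(x$unfilled)) sprintf(" (%d unfillable)", length(x$unfilled)) else ""
  ))
  invisible(x)
}

#' @export
tidy.fill_result <- function(x, ...) x$metrics

#' @export
glance.fill_result <- function(x, ...) {
  test <- dplyr::filter(x$metrics, .data$set == "test")
  tibble::tibble(
    method = x$method, r2 = test$r2, rmse = test$rmse, be = test$be,
    n_filled = sum(x$data$source == "filled"), nobs = nrow(x$data)
  )
}
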