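#' Normalize a fluorescence series to relative saturation s(t)
#'
#' Subtracts the background, floors negative values at zero, and divides by
#' the per-cell maximum, yielding the relative series s(t) in [0, 1]. Values
#' are clamped to [eps, 1 - eps] (eps = 1e-6) so that log-transforms and the
#' 1 - s denominator stay finite; clamped frames are flagged.
#'
#' @param times frame times, hours (uniform grid).
#' @param intensity raw fluorescence, arbitrary units.
#' @param background scalar background level, same units; default the mean of
#'   the first three frames.
#' @param saturation intensity (net of background) at full saturation. Default
#'   `NULL` uses the observed per-cell maximum — the right choice for raw
#'   microscope traces, where dying cells reach the plateau. Supply the known
#'   plateau when available (e.g. 1 for [generate_cohort()] traces, which are
#'   in saturation units): for cells that never saturate, dividing by the
#'   observed maximum overstates s and biases the uptake scale.
#' @return A list with `times`, `s` (clamped relative series), and `clamped`
#'   (logical flags).
#' @export
normalize_series <- function(times, intensity, background = NULL,
                             saturation = NULL) {
  if (length(times) < 10L) stop("need at least 10 frames", call. = FALSE)
  if (length(intensity) != length(times))
    stop("times and intensity must have equal length", call. = FALSE)
  if (!all(is.finite(intensity))) stop("intensity must be finite",
                                       call. = FALSE)
  if (is.null(background)) background <- mean(intensity[1:3])
  net <- pmax(intensity - background, 0)
  mx <- if (is.null(saturation)) max(net) else saturation
  if (max(net) <= 0) stop("flat series: maximum does not exceed background",
                          call. = FALSE)
  s <- net / mx
  eps <- 1e-6
  clamped <- s < eps | s > 1 - eps
  list(times = times, s = pmin(pmax(s, eps), 1 - eps), clamped = clamped)
}

#' Adaptive (Wiener) local-linear smoother
#'
#' One-dimensional adaptive Wiener filter with a local linear signal model:
#' within a sliding neighborhood of `width` samples a least-squares line is
#' fitted; the estimate is `fit + max(0, v - noise) / v * (y - fit)` where `v`
#' is the local residual variance around the line. Where the residuals are at
#' the noise floor the filter returns the local linear fit (which preserves
#' trends, the feature the downstream derivative estimator needs); where the
#' signal bends faster than a line it passes the data through. The noise
#' power defaults to half the median squared successive difference, a robust
#' estimate of frame-uncorrelated noise variance under a slowly varying
#' signal.
#'
#' @param y numeric series.
#' @param width neighborhood size in samples (default 7).
#' @param noise_power noise variance; default half the median squared
#'   successive difference.
#' @return Smoothed series, same length as `y`.
#' @export
wiener_smooth <- function(y, width = 7, noise_power = NULL) {
  n <- length(y)
  if (n < width) return(y)
  half <- width %/% 2
  fit <- numeric(n); v <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    tj <- j - mean(j)
    b <- sum(tj * y[j]) / sum(tj^2)
    yj <- mean(y[j]) + b * tj
    fit[i] <- yj[j == i]
    r <- y[j] - yj
    v[i] <- sum(r^2) / max(1, length(j) - 2)
  }
  if (is.null(noise_power))
    # median |diff|^2 = 2 * qchisq(0.5, 1) * noise variance for iid noise on a
    # slowly varying signal
    noise_power <- stats::median(diff(y)^2) / (2 * stats::qchisq(0.5, 1))
  gain <- ifelse(v > 0, pmax(0, v - noise_power) / v, 0)
  fit + gain * (y - fit)
}

#' Estimate windowed PI uptake rates and damage from a relative series
#'
#' Implements the uptake pipeline: smooth `log(s)` with the adaptive Wiener
#' filter; estimate `d log(s)/dt` by ordinary least squares in non-overlapping
#' windows of `window_h` hours; convert the slope to a normalized uptake rate
#' via `slope * s / (1 - s) / a1` evaluated at the window centre (smoothed s).
#' Damage is `X = log(uptake)`. Windows where the smoothed s exceeds
#' `1 - 1e-5` (post-death saturation) or where the estimated slope is
#' non-positive are masked invalid.
#'
#' @param norm a [normalize_series()] result.
#' @param window_h window width, hours (default 7).
#' @param anchor_h age at which the window grid starts (default 20; the first
#'   20 h are an adaptation period and are not windowed).
#' @param a1 uptake prefactor, 1/h (default 1/600).
#' @param smooth_width Wiener neighborhood, samples (default 7).
#' @return A list of class `uptake_trajectory` with `window_centers` (h),
#'   `uptake` (normalized rate e^X), `damage` (X, kBT), `valid` mask, plus the
#'   dense smoothed series (`times`, `log_s_smooth`, `dense_damage`) used for
#'   death calling.
#' @export
estimate_uptake <- function(norm, window_h = 7, anchor_h = 20, a1 = 1 / 600,
                            smooth_width = 7) {
  times <- norm$times
  span <- max(times) - anchor_h
  n_win <- floor(span / window_h)
  if (n_win < 2L) stop("series must span at least two windows", call. = FALSE)
  log_s <- wiener_smooth(log(norm$s), width = smooth_width)
  s_sm <- exp(log_s)
  centers <- uptake <- rep(NA_real_, n_win)
  valid <- rep(FALSE, n_win)
  for (k in seq_len(n_win) - 1L) {
    lo <- anchor_h + k * window_h
    hi <- lo + window_h
    sel <- which(times >= lo & times < hi)
    centers[k + 1L] <- (lo + hi) / 2
    if (length(sel) < 3L) next
    slope <- stats::cov(times[sel], log_s[sel]) / stats::var(times[sel])
    # the OLS slope is centred on the mean frame time of the window; evaluate
    # the s/(1-s) factor there to keep the estimate internally consistent
    s_bar <- stats::approx(times, s_sm, xout = mean(times[sel]), rule = 2)$y
    if (s_bar > 1 - 1e-5) next  # saturated (post-death)
    u <- slope * s_bar / (1 - s_bar) / a1
    if (!is.finite(u) || u <= 0) next
    uptake[k + 1L] <- u
    valid[k + 1L] <- TRUE
  }
  # dense damage from centred differences of the smoothed log-series
  dlog <- dense_gradient(times, log_s)
  dense_u <- dlog * s_sm / (1 - s_sm) / a1
  ok_sm <- is.finite(dense_u) & dense_u > 0 & s_sm < 1 - 1e-5
  dense_damage <- rep(NA_real_, length(dense_u))
  dense_damage[ok_sm] <- log(dense_u[ok_sm])
  # sharp (unsmoothed) dense damage for death calling: backward differences of
  # the raw log-series keep the fluorescence jump at death localized to one
  # frame, where the symmetric smoother would spread it hours backwards
  log_raw <- log(norm$s)
  dlog_raw <- c(NA_real_, diff(log_raw) / diff(times))
  s_raw_mid <- exp((log_raw + c(NA_real_, log_raw[-length(log_raw)])) / 2)
  raw_u <- dlog_raw * s_raw_mid / (1 - s_raw_mid) / a1
  ok_raw <- is.finite(raw_u) & raw_u > 0 & s_raw_mid < 1 - 1e-5
  dense_damage_raw <- rep(NA_real_, length(raw_u))
  dense_damage_raw[ok_raw] <- log(raw_u[ok_raw])
  structure(list(window_centers = centers, uptake = uptake,
                 damage = if (any(valid)) log(uptake) else rep(NA_real_, n_win),
                 valid = valid,
                 times = times, log_s_smooth = log_s,
                 dense_damage = dense_damage,
                 dense_damage_raw = dense_damage_raw,
                 empty = !any(valid)),
            class = "uptake_trajectory")
}

# centred finite-difference gradient (one-sided at the ends)
dense_gradient <- function(x, y) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

#' Call the death time of a trajectory against a damage threshold
#'
#' Lifespan is the first time the dense damage estimate reaches `x_c`,
#' linearly interpolated between frames; trajectories that never cross are
#' censored at the horizon. Death calling uses the sharp (frame-difference)
#' dense damage series rather than the smoothed one: the symmetric smoother
#' spreads the fluorescence jump at death several hours backwards, whereas
#' backward differences keep it localized, giving ~1 frame resolution. In calibration mode (`known_lifespans` supplied to
#' [calibrate_threshold()]), the threshold is instead derived from the data.
#'
#' @param traj an [estimate_uptake()] result (or any list with `times` and
#'   `dense_damage`).
#' @param rule a [death_rule()].
#' @return A list with `lifespan_h` (NA if censored), `censored`, and
#'   `horizon`.
#' @export
call_death <- function(traj, rule) {
  x <- if (!is.null(traj$dense_damage_raw)) traj$dense_damage_raw else
    traj$dense_damage
  t <- traj$times
  ok <- is.finite(x)
  horizon <- max(t)
  idx <- which(ok & x >= rule$x_c)
  if (length(idx) == 0L)
    return(list(lifespan_h = NA_real_, censored = TRUE, horizon = horizon))
  i <- idx[1]
  if (i == 1L || !is.finite(x[i - 1L]) || x[i - 1L] >= rule$x_c)
    return(list(lifespan_h = t[i], censored = FALSE, horizon = horizon))
  frac <- (rule$x_c - x[i - 1L]) / (x[i] - x[i - 1L])
  list(lifespan_h = t[i - 1L] + frac * (t[i] - t[i - 1L]),
       censored = FALSE, horizon = horizon)
}

#' Calibrate the death threshold from known lifespans
#'
#' Returns the maximal damage observed before death across cells, i.e. the
#' smallest threshold that no cell exceeds while alive — the convention used
#' to fix x_c from previously established lifespans.
#'
#' @param trajs list of [estimate_uptake()] results.
#' @param known_lifespans numeric vector of lifespans, hours (NA = censored).
#' @return The calibrated threshold (kBT).
#' @export
calibrate_threshold <- function(trajs, known_lifespans) {
  stopifnot(length(trajs) == length(known_lifespans))
  mx <- -Inf
  for (i in seq_along(trajs)) {
    L <- known_lifespans[i]
    tr <- trajs[[i]]
    sel <- is.finite(tr$dense_damage) &
      (if (is.na(L)) TRUE else tr$times < L)
    if (any(sel)) mx <- max(mx, max(tr$dense_damage[sel]))
  }
  if (!is.finite(mx)) stop("no valid damage values before death", call. = FALSE)
  mx
}

#' Run the extraction pipeline over a cohort of traces
#'
#' Applies [normalize_series()], [estimate_uptake()] and [call_death()] to
#' every cell in a long-format trace table.
#'
#' @param traces data frame with columns cell_id, time_h, fluorescence.
#' @param rule a [death_rule()] for death calling.
#' @param background per-cell background level passed to [normalize_series()];
#'   default 0 (generator traces are already background-free). Use `NULL` for
#'   the first-three-frames default of raw microscope traces.
#' @param saturation known saturation plateau passed to [normalize_series()];
#'   default 1 (generator traces are in saturation units). Use `NULL` to
#'   normalize by the observed per-cell maximum, as for raw traces.
#' @param ... passed to [estimate_uptake()] (window_h, anchor_h, a1, ...).
#' @return A list with `windows` (data frame: cell_id, window_center_h,
#'   uptake, damage_kBT, valid), `lifespans` (data frame: cell_id, lifespan_h,
#'   censored), and `trajectories` (named list of `uptake_trajectory`).
#' @export
extract_cohort <- function(traces, rule, background = 0, saturation = 1,
                           ...) {
  stopifnot(all(c("cell_id", "time_h", "fluorescence") %in% names(traces)))
  ids <- unique(traces$cell_id)
  by_cell <- split(traces, factor(traces$cell_id, levels = ids))
  trajs <- vector("list", length(ids))
  names(trajs) <- ids
  win_rows <- life_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- by_cell[[i]]
    d <- d[order(d$time_h), ]
    nrm <- normalize_series(d$time_h, d$fluorescence,
                            background = background, saturation = saturation)
    tr <- estimate_uptake(nrm, ...)
    trajs[[i]] <- tr
    dd <- call_death(tr, rule)
    win_rows[[i]] <- data.frame(cell_id = ids[i],
                                window_center_h = tr$window_centers,
                                uptake = tr$uptake,
                                damage_kBT = tr$damage,
                                valid = tr$valid)
    life_rows[[i]] <- data.frame(cell_id = ids[i],
                                 lifespan_h = dd$lifespan_h,
                                 censored = dd$censored)
  }
  list(windows = do.call(rbind, win_rows),
       lifespans = do.call(rbind, life_rows),
       trajectories = trajs)
}
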