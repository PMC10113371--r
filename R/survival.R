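#' Survivorship and cumulative hazard with bootstrap confidence bands
#'
#' Kaplan-Meier product-limit survivorship (which reduces to the empirical
#' survival function when nothing is censored) via [survival::survfit()], with
#' the cumulative hazard -ln S(t), percentile bootstrap confidence bands over
#' cells, and lifespan summary statistics on uncensored lifespans.
#'
#' @param lifespans death ages, hours; `NA` allowed for censored cells when
#'   `censored` is not given.
#' @param censored logical vector; censored cells contribute at-risk time up
#'   to `horizon`.
#' @param horizon censoring time for censored cells, hours (default the
#'   largest observed lifespan).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return An object of class `survival_curve`: data frame `curve` (time_h,
#'   S, cumhaz, ci_low, ci_high, n_at_risk) plus `lifespan_mean`,
#'   `lifespan_cv`, `quantiles` (5/50/95%), `n_events`, `n_censored`.
#' @export
survival_curves <- function(lifespans, censored = NULL, horizon = NULL,
                            n_boot = 1000, seed = 1) {
  if (is.null(censored)) censored <- is.na(lifespans)
  if (all(censored)) stop("all cells censored: no survival curve",
                          call. = FALSE)
  if (sum(!censored) < 2L) stop("need at least 2 death events", call. = FALSE)
  if (sum(!censored) < 10L)
    warning("fewer than 10 death events; curve will be unstable",
            call. = FALSE)
  if (is.null(horizon)) horizon <- max(lifespans, na.rm = TRUE)
  time <- ifelse(censored, horizon, lifespans)
  event <- as.integer(!censored)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  grid <- sort(unique(c(0, fit$time)))
  S_at <- function(tt, ee) {
    f <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    idx <- findInterval(grid, f$time)
    c(1, f$surv)[idx + 1L]
  }
  S <- S_at(time, event)
  set.seed(as.integer(seed %% 2147483647))
  n <- length(time)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- S_at(time[idx], event[idx])
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  n_at_risk <- vapply(grid, function(g) sum(time >= g), integer(1))
  dead <- lifespans[!censored]
  structure(list(
    curve = data.frame(time_h = grid, S = S, cumhaz = -log(S),
                       ci_low = ci[1, ], ci_high = ci[2, ],
                       n_at_risk = n_at_risk),
    lifespan_mean = mean(dead),
    lifespan_cv = stats::sd(dead) / mean(dead),
    quantiles = stats::quantile(dead, c(0.05, 0.5, 0.95)),
    n_events = sum(event), n_censored = sum(censored),
    times = time, events = event),
    class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d deaths, %d censored\n",
              x$n_events, x$n_censored))
  cat(sprintf("  mean lifespan %.1f h (CV %.2f); 5/50/95%% quantiles %.0f/%.0f/%.0f h\n",
              x$lifespan_mean, x$lifespan_cv,
              x$quantiles[1], x$quantiles[2], x$quantiles[3]))
  invisible(x)
}

#' Gompertz slope from the cumulative hazard
#'
#' For a Gompertz process (hazard h0 * exp(g t)) the log cumulative hazard is
#' asymptotically linear in age with slope g. This fits
#' `ln(cumhaz) ~ age` by OLS within `fit_window` and returns the slope with a
#' percentile bootstrap CI over cells.
#'
#' @param curve a [survival_curves()] result.
#' @param fit_window ages (h) bounding the fit; default the 10% and 90% death
#'   quantiles, the exponential regime of a sigmoidal survival curve.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return A list with `slope` (1/h), `ci`, `n_ages`, `fit_window`.
#' @export
gompertz_slope <- function(curve, fit_window = NULL, n_boot = 1000, seed = 1) {
  stopifnot(inherits(curve, "survival_curve"))
  dead <- curve$times[curve$events == 1]
  if (is.null(fit_window))
    fit_window <- stats::quantile(dead, c(0.1, 0.9), names = FALSE)
  slope_of <- function(tt, ee) {
    f <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    keep <- f$time >= fit_window[1] & f$time <= fit_window[2] &
      f$surv > 0 & f$surv < 1
    if (sum(keep) < 5L) return(NA_real_)
    lch <- log(-log(f$surv[keep]))
    ages <- f$time[keep]
    stats::cov(ages, lch) / stats::var(ages)
  }
  slope <- slope_of(curve$times, curve$events)
  if (!is.finite(slope))
    stop("fewer than 5 event ages inside the fit window", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  n <- length(curve$times)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    slope_of(curve$times[idx], curve$events[idx])
  }, numeric(1))
  list(slope = slope,
       ci = stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE),
       n_ages = sum(dead >= fit_window[1] & dead <= fit_window[2]),
       fit_window = fit_window)
}

#' Compare two survival cohorts
#'
#' Mean-lifespan ratio and Gompertz-slope ratio (B relative to A) with
#' percentile bootstrap CIs, and the normalized-age overlay distance: the
#' maximal vertical gap between the two survivorship curves plotted against
#' age / mean lifespan. Processes whose parameters rescale time leave the
#' normalized overlay unchanged, so a small overlay distance means the two
#' cohorts share a survival-curve shape.
#'
#' @param curve_a,curve_b [survival_curves()] results (A = reference).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return A list with `mean_ratio` (+ ci), `slope_ratio` (+ ci),
#'   `overlay_distance`, `raw_distance` (max gap on the unnormalized age
#'   axis).
#' @export
compare_cohorts <- function(curve_a, curve_b, n_boot = 500, seed = 1) {
  stopifnot(inherits(curve_a, "survival_curve"),
            inherits(curve_b, "survival_curve"))
  ratio_boot <- function(stat_fun) {
    set.seed(as.integer(seed %% 2147483647))
    va <- stat_fun(curve_a$times, curve_a$events)
    vb <- stat_fun(curve_b$times, curve_b$events)
    na <- length(curve_a$times); nb <- length(curve_b$times)
    reps <- vapply(seq_len(n_boot), function(b) {
      ia <- sample.int(na, na, replace = TRUE)
      ib <- sample.int(nb, nb, replace = TRUE)
      stat_fun(curve_b$times[ib], curve_b$events[ib]) /
        stat_fun(curve_a$times[ia], curve_a$events[ia])
    }, numeric(1))
    list(est = vb / va,
         ci = stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE))
  }
  mean_stat <- function(tt, ee) mean(tt[ee == 1])
  slope_stat <- function(tt, ee) {
    dead <- tt[ee == 1]
    fw <- stats::quantile(dead, c(0.1, 0.9), names = FALSE)
    f <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    keep <- f$time >= fw[1] & f$time <= fw[2] & f$surv > 0 & f$surv < 1
    if (sum(keep) < 5L) return(NA_real_)
    stats::cov(f$time[keep], log(-log(f$surv[keep]))) /
      stats::var(f$time[keep])
  }
  mr <- ratio_boot(mean_stat)
  sr <- ratio_boot(slope_stat)
  gap <- function(normalize) {
    grid <- seq(0.01, 2, by = 0.01)
    sa <- step_surv(curve_a, if (normalize) curve_a$lifespan_mean else 1, grid)
    sb <- step_surv(curve_b, if (normalize) curve_b$lifespan_mean else 1, grid)
    max(abs(sa - sb))
  }
  list(mean_ratio = mr$est, mean_ratio_ci = mr$ci,
       slope_ratio = sr$est, slope_ratio_ci = sr$ci,
       overlay_distance = gap(TRUE),
       raw_distance = {
         grid <- seq(0, max(curve_a$curve$time_h, curve_b$curve$time_h),
                     length.out = 400)
         max(abs(step_surv(curve_a, 1, grid) - step_surv(curve_b, 1, grid)))
       })
}

step_surv <- function(curve, scale, grid) {
  xs <- curve$curve$time_h / scale
  ys <- curve$curve$S
  if (xs[1] > 0) { xs <- c(0, xs); ys <- c(1, ys) }
  stats::approx(xs, ys, xout = grid, method = "constant", rule = 2)$y
}
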