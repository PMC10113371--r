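#' Cross-sectional damage statistics with bootstrap errors
#'
#' For each requested age, computes mean, standard deviation, coefficient of
#' variation and skewness of the damage observable over cells that are alive
#' at that age (lifespan > age, or censored) and have a valid window there.
#' Standard errors come from bootstrapping cells, not windows.
#'
#' @param windows data frame (cell_id, window_center_h, uptake, damage_kBT,
#'   valid), as produced by [extract_cohort()] or [ensemble_windows()].
#' @param lifespans data frame (cell_id, lifespan_h, censored); `NA`
#'   lifespan = censored.
#' @param ages ages (window centres, h) to evaluate; default all present.
#' @param observable `"uptake"` (e^X; the convention for mean/SD/CV/skewness)
#'   or `"damage"` (X).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with one row per age: n_alive, mean, sd, cv, skewness
#'   and their bootstrap standard errors (`*_se`).
#' @export
cross_sectional_stats <- function(windows, lifespans, ages = NULL,
                                  observable = c("uptake", "damage"),
                                  n_boot = 1000, seed = 1) {
  observable <- match.arg(observable)
  present <- sort(unique(windows$window_center_h))
  if (is.null(ages)) ages <- present
  if (!all(ages %in% present))
    stop("requested age(s) outside the window grid", call. = FALSE)
  life <- lifespans$lifespan_h[match(windows$cell_id, lifespans$cell_id)]
  alive <- is.na(life) | life > windows$window_center_h
  rows <- lapply(ages, function(a) {
    sel <- windows$window_center_h == a & windows$valid & alive
    v <- if (observable == "uptake") windows$uptake[sel] else
      windows$damage_kBT[sel]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop(sprintf("fewer than 2 alive cells with valid windows at %g h", a),
           call. = FALSE)
    est <- c(mean = mean(v), sd = stats::sd(v), cv = stats::sd(v) / mean(v),
             skewness = sample_skewness(v))
    se <- boot_se(v, function(x) c(mean(x), stats::sd(x),
                                   stats::sd(x) / mean(x),
                                   sample_skewness(x)),
                  n_boot, seed + round(a * 10))
    data.frame(age_h = a, n_alive = length(v),
               mean = est[["mean"]], mean_se = se[1],
               sd = est[["sd"]], sd_se = se[2],
               cv = est[["cv"]], cv_se = se[3],
               skewness = est[["skewness"]], skewness_se = se[4])
  })
  do.call(rbind, rows)
}

# adjusted Fisher-Pearson sample skewness (the n/((n-1)(n-2)) * sum(z^3) form);
# 0 by convention for constant samples
sample_skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 3L || s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

boot_se <- function(x, stat_fun, n_boot, seed) {
  set.seed(as.integer(seed %% 2147483647))
  n <- length(x)
  reps <- vapply(seq_len(n_boot),
                 function(i) stat_fun(x[sample.int(n, n, replace = TRUE)]),
                 numeric(length(stat_fun(x))))
  if (is.null(dim(reps))) stats::sd(reps) else apply(reps, 1, stats::sd)
}

#' Lagged autocorrelation of damage across cells
#'
#' Pearson correlation, over cells alive and valid at both ages, between the
#' damage observable at `age` and at `age + lag_h`. A rising lag correlation
#' with age indicates increasing persistence of damage levels.
#'
#' @inheritParams cross_sectional_stats
#' @param age base age (a window centre, h).
#' @param lag_h lag, hours (default 7, one window).
#' @param observable `"damage"` (default, the convention for persistence) or
#'   `"uptake"`.
#' @return A list with `r`, `se` (cell bootstrap), `n_pairs`.
#' @export
damage_autocorrelation <- function(windows, lifespans, age, lag_h = 7,
                                   observable = c("damage", "uptake"),
                                   n_boot = 1000, seed = 1) {
  observable <- match.arg(observable)
  life <- lifespans$lifespan_h[match(windows$cell_id, lifespans$cell_id)]
  alive2 <- is.na(life) | life > age + lag_h
  col <- if (observable == "damage") "damage_kBT" else "uptake"
  w1 <- windows[windows$window_center_h == age & windows$valid & alive2, ]
  w2 <- windows[windows$window_center_h == age + lag_h & windows$valid &
                  alive2, ]
  shared <- intersect(w1$cell_id, w2$cell_id)
  if (length(shared) < 3L)
    stop("fewer than 3 cells alive and valid at both ages", call. = FALSE)
  v1 <- w1[[col]][match(shared, w1$cell_id)]
  v2 <- w2[[col]][match(shared, w2$cell_id)]
  r <- stats::cor(v1, v2)
  set.seed(as.integer((seed + round(age * 10)) %% 2147483647))
  n <- length(shared)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(v1[idx], v2[idx]))
  }, numeric(1))
  list(r = r, se = stats::sd(reps, na.rm = TRUE), n_pairs = n)
}

#' Initial-condition analysis: do starting states predict lifespan?
#'
#' Spearman correlations of lifespan with initial damage and cell-cycle
#' covariates; the cohort split at an initial-uptake threshold into high- and
#' low-damage groups with per-group correlations; and a multiple OLS
#' regression of lifespan on the initial conditions reporting the fraction of
#' lifespan variance explained (R^2), for all cells and for the low-damage
#' group.
#'
#' @param lifespans data frame (cell_id, lifespan_h, censored); censored cells
#'   are excluded from correlations.
#' @param initial_uptake named (by cell_id) or cell-aligned numeric vector of
#'   initial normalized PI uptake rates.
#' @param covariates data frame with cell_id and (optionally)
#'   initial_size_um, last_division_h, n_divisions; missing values handled by
#'   pairwise deletion, with pair counts reported.
#' @param split initial-uptake threshold separating high- from low-damage
#'   cells (default 4).
#' @return A list of class `initial_condition_report`: `spearman` (table of
#'   label, r, n, p), `split`, `r_high`, `r_low` (with group sizes),
#'   `regression_r2_all`, `regression_r2_low`, `n_analyzed`.
#' @export
initial_condition_analysis <- function(lifespans, initial_uptake, covariates,
                                       split = 4) {
  dead <- lifespans[!lifespans$censored & !is.na(lifespans$lifespan_h), ]
  if (nrow(dead) < 10L) stop("need >= 10 uncensored cells", call. = FALSE)
  u0 <- initial_uptake
  if (!is.null(names(u0))) u0 <- u0[dead$cell_id]
  else u0 <- u0[match(dead$cell_id, lifespans$cell_id)]
  L <- dead$lifespan_h
  cov <- covariates[match(dead$cell_id, covariates$cell_id), , drop = FALSE]
  sp_one <- function(x, label) {
    ok <- is.finite(x) & is.finite(L)
    ct <- suppressWarnings(
      stats::cor.test(x[ok], L[ok], method = "spearman", exact = FALSE))
    data.frame(label = label, r = unname(ct$estimate), n = sum(ok),
               p = ct$p.value)
  }
  sp <- rbind(
    sp_one(u0, "initial_damage"),
    if ("initial_size_um" %in% names(cov))
      sp_one(cov$initial_size_um, "initial_size"),
    if ("last_division_h" %in% names(cov))
      sp_one(cov$last_division_h, "last_division_time"),
    if ("n_divisions" %in% names(cov))
      sp_one(cov$n_divisions, "n_divisions"))
  hi <- u0 > split
  grp <- function(sel) {
    if (sum(sel) < 3L) return(list(r = NA_real_, n = sum(sel), p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(u0[sel], L[sel],
                                           method = "spearman", exact = FALSE))
    list(r = unname(ct$estimate), n = sum(sel), p = ct$p.value)
  }
  reg_r2 <- function(sel) {
    dd <- data.frame(L = L[sel], u0 = u0[sel])
    for (nm in intersect(c("initial_size_um", "last_division_h",
                           "n_divisions"), names(cov)))
      dd[[nm]] <- cov[[nm]][sel]
    # degenerate (constant) regressors are dropped with a warning
    keep <- vapply(dd, function(x) length(unique(x[is.finite(x)])) > 1,
                   logical(1))
    if (!all(keep[-1])) warning("dropping constant regressor(s): ",
                                paste(names(dd)[-1][!keep[-1]],
                                      collapse = ", "), call. = FALSE)
    dd <- dd[, keep, drop = FALSE]
    # last divisions are absent for never-divided cells; treat as division at
    # loading (time 0) rather than dropping those cells
    if ("last_division_h" %in% names(dd))
      dd$last_division_h[!is.finite(dd$last_division_h)] <- 0
    fit <- stats::lm(L ~ ., data = dd, na.action = stats::na.omit)
    summary(fit)$r.squared
  }
  structure(list(spearman = sp, split = split,
                 r_high = grp(hi), r_low = grp(!hi),
                 regression_r2_all = reg_r2(rep(TRUE, length(L))),
                 regression_r2_low = reg_r2(!hi),
                 n_analyzed = length(L)),
            class = "initial_condition_report")
}

#' @export
print.initial_condition_report <- function(x, ...) {
  cat("Initial-condition analysis (", x$n_analyzed, "uncensored cells)\n")
  print(x$spearman, row.names = FALSE)
  cat(sprintf("  split at uptake %g: high r=%.2f (n=%d), low r=%.2f (n=%d)\n",
              x$split, x$r_high$r, x$r_high$n, x$r_low$r, x$r_low$n))
  cat(sprintf("  regression R2: all %.3f, low-damage %.3f\n",
              x$regression_r2_all, x$regression_r2_low))
  invisible(x)
}

#' Damage aligned on remaining lifespan
#'
#' Re-indexes each dead cell's windows by time before its death and reports
#' the dispersion (sd of X) per remaining-lifespan bin: trajectories become
#' less variable as death approaches.
#'
#' @inheritParams cross_sectional_stats
#' @param bin_h width of remaining-lifespan bins, hours (default 7, one
#'   window).
#' @return Data frame (time_before_death_h = bin midpoint, n, mean_damage,
#'   sd_damage).
#' @export
remaining_lifespan_view <- function(windows, lifespans, bin_h = 7) {
  dead <- lifespans[!lifespans$censored & !is.na(lifespans$lifespan_h), ]
  w <- windows[windows$valid & windows$cell_id %in% dead$cell_id, ]
  L <- dead$lifespan_h[match(w$cell_id, dead$cell_id)]
  rem <- L - w$window_center_h
  w <- w[rem > 0, ]; rem <- rem[rem > 0]
  bins <- floor(rem / bin_h)
  agg <- split(w$damage_kBT, bins)
  mids <- (as.numeric(names(agg)) + 0.5) * bin_h
  data.frame(time_before_death_h = mids,
             n = vapply(agg, length, integer(1)),
             mean_damage = vapply(agg, mean, numeric(1)),
             sd_damage = vapply(agg, stats::sd, numeric(1)))
}

#' Twilight analysis: remaining lifespan after crossing a sub-lethal threshold
#'
#' For every cell that crosses `threshold_x` and subsequently dies, records
#' the age at first crossing and the remaining lifespan, and fits their
#' relation by OLS. A negative slope means twilight shortens with age: late
#' crossers have less time left than early crossers.
#'
#' @param trajs either a named list of `uptake_trajectory` objects (dense
#'   damage used for crossing detection) or a windows data frame (window
#'   damage used).
#' @param lifespans data frame (cell_id, lifespan_h, censored).
#' @param threshold_x sub-lethal damage threshold, kBT; must be below the
#'   death threshold `x_c`.
#' @param x_c death threshold for the precondition check.
#' @param n_boot bootstrap replicates for the slope CI (default 1000).
#' @param seed RNG seed.
#' @return A list of class `twilight_result`: `table` (cell_id, crossing_age,
#'   remaining_lifespan), `slope`, `ci` (95% percentile bootstrap over cells),
#'   `n`.
#' @export
twilight <- function(trajs, lifespans, threshold_x, x_c = 3.5,
                     n_boot = 1000, seed = 1) {
  if (threshold_x >= x_c)
    stop("threshold_x must be below the death threshold x_c", call. = FALSE)
  dead <- lifespans[!lifespans$censored & !is.na(lifespans$lifespan_h), ]
  crossing_age <- function(id) {
    if (is.data.frame(trajs)) {
      w <- trajs[trajs$cell_id == id & trajs$valid, ]
      i <- which(w$damage_kBT >= threshold_x)
      if (!length(i)) return(NA_real_)
      w$window_center_h[min(i)]
    } else {
      tr <- trajs[[id]]
      x <- if (!is.null(tr$dense_damage_raw)) tr$dense_damage_raw else
        tr$dense_damage
      i <- which(is.finite(x) & x >= threshold_x)
      if (!length(i)) return(NA_real_)
      tr$times[min(i)]
    }
  }
  ages <- vapply(dead$cell_id, crossing_age, numeric(1))
  ok <- is.finite(ages) & ages < dead$lifespan_h
  tab <- data.frame(cell_id = dead$cell_id[ok], crossing_age = ages[ok],
                    remaining_lifespan = dead$lifespan_h[ok] - ages[ok])
  if (nrow(tab) < 10L)
    stop("fewer than 10 cells cross the threshold and die", call. = FALSE)
  slope_of <- function(d) {
    if (stats::var(d$crossing_age) == 0) return(0)
    stats::cov(d$crossing_age, d$remaining_lifespan) /
      stats::var(d$crossing_age)
  }
  set.seed(as.integer(seed %% 2147483647))
  reps <- vapply(seq_len(n_boot), function(i)
    slope_of(tab[sample.int(nrow(tab), nrow(tab), replace = TRUE), ]),
    numeric(1))
  structure(list(table = tab, slope = slope_of(tab),
                 ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
                 n = nrow(tab)),
            class = "twilight_result")
}

#' @export
print.twilight_result <- function(x, ...) {
  cat(sprintf(
    "Twilight: slope of remaining lifespan vs crossing age = %.3f h/h\n",
    x$slope))
  cat(sprintf("  95%% CI [%.3f, %.3f], n = %d crossing cells\n",
              x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Windowed observations from a simulated ensemble
#'
#' Subsamples a free-running or absorbed [simulate_paths()] ensemble to the
#' analysis window grid, producing the same windows/lifespans tables that
#' [extract_cohort()] yields from traces — the bridge between model
#' simulations and the cohort statistics.
#'
#' @param ens a `trajectory_ensemble`.
#' @param centers window centre ages, h (default the 8 standard windows
#'   23.5, 30.5, ..., 72.5).
#' @param average half-width, h: when > 0, the window value is
#'   `log(mean(exp(X)))` over grid points within `centers +- average`
#'   (mimicking windowed estimation); when 0, the instantaneous X at the
#'   centre is used.
#' @return A list with `windows` and `lifespans` data frames (cell ids
#'   `sim_0001`, ...).
#' @export
ensemble_windows <- function(ens, centers = seq(23.5, 72.5, by = 7),
                             average = 3.5) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  n <- nrow(ens$paths)
  ids <- sprintf("sim_%05d", seq_len(n))
  rows <- lapply(centers, function(cc) {
    sel <- if (average > 0)
      which(ens$times >= cc - average & ens$times < cc + average)
    else which.min(abs(ens$times - cc))
    xm <- ens$paths[, sel, drop = FALSE]
    x <- log(rowMeans(exp(xm)))
    data.frame(cell_id = ids, window_center_h = cc,
               uptake = exp(x), damage_kBT = x,
               valid = is.finite(x))
  })
  windows <- do.call(rbind, rows)
  lifespans <- data.frame(
    cell_id = ids,
    lifespan_h = if (!is.null(ens$death_times)) ens$death_times else
      NA_real_,
    censored = if (!is.null(ens$death_times)) is.na(ens$death_times) else TRUE)
  list(windows = windows, lifespans = lifespans)
}
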