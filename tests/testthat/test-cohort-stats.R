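make_windows <- function(values_by_age, lifespans = NULL) {
  # values_by_age: named list age -> per-cell values (same cells each age)
  n <- length(values_by_age[[1]])
  ids <- sprintf("w%03d", seq_len(n))
  w <- do.call(rbind, lapply(names(values_by_age), function(a)
    data.frame(cell_id = ids, window_center_h = as.numeric(a),
               uptake = exp(values_by_age[[a]]),
               damage_kBT = values_by_age[[a]], valid = TRUE)))
  if (is.null(lifespans)) lifespans <- rep(NA_real_, n)
  list(windows = w,
       lifespans = data.frame(cell_id = ids, lifespan_h = lifespans,
                              censored = is.na(lifespans)))
}

test_that("cross-sectional statistics match direct formula evaluation", {
  v <- c(1, 2, 3, 4, 100)
  d <- make_windows(list(`30` = log(v)))
  cs <- cross_sectional_stats(d$windows, d$lifespans, ages = 30,
                              observable = "uptake", n_boot = 50, seed = 1)
  expect_equal(cs$mean, 22)
  expect_equal(cs$sd, sd(v))
  expect_equal(cs$cv, sd(v) / 22)
  # adjusted Fisher-Pearson skewness, brute-force formula
  n <- 5
  g <- n / ((n - 1) * (n - 2)) * sum(((v - mean(v)) / sd(v))^3)
  expect_equal(cs$skewness, g)
  # degenerate: identical values
  d2 <- make_windows(list(`30` = rep(log(2), 6)))
  cs2 <- cross_sectional_stats(d2$windows, d2$lifespans, ages = 30,
                               n_boot = 20, seed = 1)
  expect_equal(cs2$sd, 0); expect_equal(cs2$cv, 0)
  expect_equal(cs2$skewness, 0)
  expect_error(cross_sectional_stats(d$windows, d$lifespans, ages = 99),
               "window grid")
})

test_that("alive-at-age filtering excludes dead cells", {
  vals <- list(`30` = log(c(1, 2, 3, 4)), `44` = log(c(2, 3, 4, 5)))
  d <- make_windows(vals, lifespans = c(35, NA, NA, NA))
  cs <- cross_sectional_stats(d$windows, d$lifespans, observable = "uptake",
                              n_boot = 20, seed = 1)
  expect_equal(cs$n_alive, c(4, 3))  # first cell dead by 44 h
  expect_equal(cs$mean[2], mean(c(3, 4, 5)))
})

test_that("autocorrelation: persistence 1, shuffled ~ 0", {
  set.seed(4)
  x <- stats::rnorm(200, 0, 1)
  d <- make_windows(list(`30` = x, `37` = x + 2))  # frozen heterogeneity
  ac <- damage_autocorrelation(d$windows, d$lifespans, age = 30, n_boot = 50,
                               seed = 2)
  expect_equal(ac$r, 1)
  expect_equal(ac$n_pairs, 200)
  d2 <- make_windows(list(`30` = x, `37` = sample(x)))
  ac2 <- damage_autocorrelation(d2$windows, d2$lifespans, age = 30,
                                n_boot = 50, seed = 2)
  expect_lt(abs(ac2$r), 2 / sqrt(200))
  expect_error(damage_autocorrelation(d$windows, d$lifespans, age = 99),
               "3 cells")
})

test_that("Spearman correlations behave and are monotone-invariant", {
  n <- 60
  u0 <- exp(seq(-1, 2, length.out = n))
  L <- 120 - 10 * seq_len(n)  # strictly decreasing in initial damage
  lifespans <- data.frame(cell_id = sprintf("w%03d", 1:n), lifespan_h = L,
                          censored = FALSE)
  cov <- data.frame(cell_id = lifespans$cell_id,
                    initial_size_um = stats::rnorm(n, 3, 0.5))
  rep1 <- initial_condition_analysis(lifespans, u0, cov, split = 4)
  expect_equal(rep1$spearman$r[rep1$spearman$label == "initial_damage"], -1)
  # strictly monotone transform of the regressor leaves Spearman unchanged
  rep2 <- initial_condition_analysis(lifespans, u0^3, cov, split = 4^3)
  expect_equal(rep1$spearman$r[1], rep2$spearman$r[1])
  expect_equal(rep1$r_high$n + rep1$r_low$n, n)
})

test_that("independent covariates explain little lifespan variance", {
  set.seed(12)
  n <- 500
  lifespans <- data.frame(cell_id = sprintf("w%03d", 1:n),
                          lifespan_h = stats::rnorm(n, 80, 15),
                          censored = FALSE)
  u0 <- exp(stats::rnorm(n, 0, 0.5))
  cov <- data.frame(cell_id = lifespans$cell_id,
                    initial_size_um = stats::rnorm(n, 3, 0.5),
                    last_division_h = stats::runif(n, 0, 10),
                    n_divisions = stats::rpois(n, 1.2))
  rep <- initial_condition_analysis(lifespans, u0, cov)
  expect_lt(rep$regression_r2_all, 0.03)
  # degenerate regressor dropped with a warning
  cov$n_divisions <- 1L
  # one warning per regression (all cells, low-damage group)
  expect_warning(expect_warning(
    initial_condition_analysis(lifespans, u0, cov), "constant"), "constant")
})

test_that("remaining-lifespan alignment measures dispersion before death", {
  vals <- list(`23.5` = c(0, 0), `30.5` = c(1, 1), `37.5` = c(2, 2))
  d <- make_windows(vals, lifespans = c(44, 44))
  rl <- remaining_lifespan_view(d$windows, d$lifespans)
  expect_true(all(rl$sd_damage == 0))  # identical cells -> no dispersion
  expect_equal(rl$n, rep(2, 3))
  # MP-SR ensemble: dispersion shrinks close to death
  p <- wildtype_params()
  ens <- simulate_paths(p, n = 800, t0 = 20, t1 = 120, dt = 0.05, seed = 6,
                        rule = death_rule(3.5))
  ew <- ensemble_windows(ens, centers = seq(23.5, 100.5, by = 7))
  rl2 <- remaining_lifespan_view(ew$windows, ew$lifespans)
  sd_near <- rl2$sd_damage[rl2$time_before_death_h == 3.5]
  sd_far <- rl2$sd_damage[rl2$time_before_death_h == 38.5]
  expect_lt(sd_near, sd_far)
})

test_that("twilight shortens with age in simulated cohorts", {
  p <- wildtype_params()
  ens <- simulate_paths(p, n = 500, t0 = 20, t1 = 140, dt = 0.05, seed = 10,
                        rule = death_rule(3.5))
  # dense crossing detection on the simulated paths
  trajs <- lapply(seq_len(500), function(i)
    list(times = ens$times, dense_damage_raw = ens$paths[i, ]))
  names(trajs) <- sprintf("sim_%05d", 1:500)
  lifespans <- data.frame(cell_id = names(trajs),
                          lifespan_h = ens$death_times,
                          censored = is.na(ens$death_times))
  tw <- twilight(trajs, lifespans, threshold_x = 2, x_c = 3.5, n_boot = 400,
                 seed = 3)
  expect_lt(tw$slope, 0)
  expect_lt(tw$ci[2], 0)   # CI excludes zero
  # identical cells: zero slope by convention
  trajs2 <- list(a = list(times = 0:50, dense_damage_raw = seq(0, 5, 0.1)),
                 b = list(times = 0:50, dense_damage_raw = seq(0, 5, 0.1)))
  ls2 <- data.frame(cell_id = c("a", "b"), lifespan_h = c(40, 40),
                    censored = FALSE)
  expect_error(twilight(trajs2, ls2, threshold_x = 2, x_c = 3.5),
               "fewer than 10")
  expect_error(twilight(trajs, lifespans, threshold_x = 4, x_c = 3.5),
               "below the death threshold")
})

test_that("bootstrap standard errors shrink roughly as 1/sqrt(n)", {
  set.seed(30)
  base <- stats::rlnorm(800, 0, 0.8)
  se_at <- function(n) {
    d <- make_windows(list(`30` = log(base[seq_len(n)])))
    cross_sectional_stats(d$windows, d$lifespans, ages = 30,
                          observable = "uptake", n_boot = 400,
                          seed = 5)$mean_se
  }
  ratio <- se_at(100) / se_at(400)
  expect_gt(ratio, 1.4); expect_lt(ratio, 2.9)  # ideal: 2
})
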