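test_that("pure Brownian transitions get the exact normal log-density", {
  # eta = beta = eta0 = 0: X is Brownian motion with variance 2 sigma t
  th <- c(eta = 0, beta = 1e-300, sigma = 0.2, a = 0.33, kappa = 0.29,
          eta0 = 0)
  tr <- data.frame(cell_id = "c1", t0 = c(0, 1, 5), x0 = c(0, 0.4, -1),
                   t1 = c(1, 3, 12), x1 = c(0.4, -1, 0.5))
  ll <- transition_loglik(tr, th, fit_config())
  exact <- sum(stats::dnorm(tr$x1, tr$x0, sqrt(2 * 0.2 * (tr$t1 - tr$t0)),
                            log = TRUE))
  expect_equal(as.numeric(ll), exact, tolerance = 1e-12)
})

test_that("Gaussian backend matches the exact OU transition for linear drift", {
  # freeze the removal in its linear regime around kappa with tiny a so that
  # G(x) = eta0 - beta/2 - (beta a / 4) (x - kappa): an exact OU process
  beta <- 1.2; a <- 0.08; kappa <- 0; sigma <- 0.15; eta0 <- 0.6
  th <- c(eta = 0, beta = beta, sigma = sigma, a = a, kappa = kappa,
          eta0 = eta0)
  rate <- beta * a / 4
  mu_inf <- (eta0 - beta / 2) / rate  # fixed point of the linearized drift
  tr <- data.frame(cell_id = "c1", t0 = c(0, 0), x0 = c(0.2, -0.4),
                   t1 = c(2, 5), x1 = c(0.5, 0.1))
  gap <- tr$t1 - tr$t0
  m <- mu_inf + (tr$x0 - mu_inf) * exp(-rate * gap)
  v <- sigma / rate * (1 - exp(-2 * rate * gap))
  exact <- sum(stats::dnorm(tr$x1, m, sqrt(v), log = TRUE))
  ll <- as.numeric(transition_loglik(tr, th, fit_config(sub_step_h = 0.25)))
  # the logistic is only locally linear; small a keeps curvature negligible
  expect_equal(ll, exact, tolerance = 1e-3)
})

test_that("simulated-likelihood backend converges to the Gaussian one", {
  th <- c(eta = 2e-3, beta = 1.12, sigma = 0.157, a = 0.33, kappa = 0.29,
          eta0 = 0.4)
  set.seed(3)
  tr <- data.frame(cell_id = sprintf("c%d", 1:20),
                   t0 = 30, x0 = stats::rnorm(20, 0, 1),
                   t1 = 31, x1 = stats::rnorm(20, 0.1, 0.6))
  cfg_kde <- fit_config(backend = "sim_kde", sims_per_transition = 8000,
                        seed = 5)
  ll_kde <- transition_loglik(tr, th, cfg_kde)
  ll_g <- transition_loglik(tr, th, fit_config(sub_step_h = 0.1))
  expect_lt(abs(as.numeric(ll_kde) - as.numeric(ll_g)) / nrow(tr), 0.05)
  # deterministic given the seed (common random numbers)
  ll_kde2 <- transition_loglik(tr, th, cfg_kde)
  expect_identical(as.numeric(ll_kde), as.numeric(ll_kde2))
})

test_that("log-likelihood is exchangeable over cells and transitions", {
  obs <- make_damage_obs(n = 12, t0 = 20, t1 = 35, seed = 4)
  tr <- transition_table(obs)
  th <- unlist(wt)
  cfg <- fit_config()
  ll1 <- as.numeric(transition_loglik(tr, th, cfg))
  perm <- tr[sample.int(nrow(tr)), ]
  perm$cell_id <- rev(perm$cell_id)
  ll2 <- as.numeric(transition_loglik(perm, th, cfg))
  expect_equal(ll1, ll2, tolerance = 1e-10)
  expect_error(transition_loglik(tr[0, ], th, cfg), "no transitions")
})

test_that("the likelihood peaks at the generating parameters", {
  obs <- make_damage_obs(n = 120, t0 = 20, t1 = 70, seed = 15)
  tr <- transition_table(obs)
  cfg <- fit_config()
  ll_true <- as.numeric(transition_loglik(tr, wt, cfg))
  for (nm in c("eta", "beta", "sigma", "a", "eta0")) {
    for (fac in c(0.5, 1.5)) {
      th <- unlist(wt)
      th[nm] <- th[nm] * fac
      expect_lt(as.numeric(transition_loglik(tr, th, cfg)), ll_true,
                label = sprintf("LL(%s x %.1f)", nm, fac))
    }
  }
})

test_that("interval-halving search recovers well-identified parameters", {
  obs <- make_damage_obs(n = 150, t0 = 20, t1 = 80, seed = 23)
  tr <- transition_table(obs)
  fit <- fit_mpsr(tr, fit_config(max_iterations = 18, n_boot = 100,
                                 seed = 2))
  est <- unlist(fit$theta_hat)
  # eta and sigma are strongly identified at this size; the removal-curve
  # parameters share a likelihood ridge and get looser bounds
  expect_equal(unname(est["sigma"]), wt$sigma, tolerance = 0.08)
  expect_equal(unname(est["eta"]), wt$eta, tolerance = 0.25)
  expect_equal(unname(est["beta"]), wt$beta, tolerance = 0.5)
  expect_gt(fit$loglik,
            as.numeric(transition_loglik(tr, wt, fit_config())) - 3)
  expect_identical(fit$n_cells, 150L)
  expect_identical(fit$n_transitions, nrow(tr))
})

test_that("fits are reproducible and write valid JSON", {
  obs <- make_damage_obs(n = 25, t0 = 20, t1 = 40, seed = 5)
  tr <- transition_table(obs)
  cfg <- fit_config(max_iterations = 6, n_boot = 50, seed = 31)
  f1 <- fit_mpsr(tr, cfg)
  f2 <- fit_mpsr(tr, cfg)
  expect_equal(unlist(f1$theta_hat), unlist(f2$theta_hat))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(f1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$theta_hat$sigma, f1$theta_hat$sigma)
  expect_equal(back$n_transitions, nrow(tr))
})

test_that("transition tables drop invalid windows and keep cell structure", {
  w <- data.frame(cell_id = c("a", "a", "a", "b", "b"),
                  window_center_h = c(23.5, 30.5, 37.5, 23.5, 30.5),
                  damage_kBT = c(0.1, 0.3, NA, -0.2, 0.2),
                  valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  tr <- transition_table(w)
  expect_identical(nrow(tr), 1L)  # only a: 23.5 -> 30.5 survives
  expect_equal(tr$x0, 0.1)
  expect_equal(tr$t1 - tr$t0, 7)
})
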