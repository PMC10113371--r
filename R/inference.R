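#' Transition table from windowed damage observations
#'
#' Converts a windows data frame (cell_id, window_center_h or time_h,
#' damage_kBT, valid) into the consecutive-pair transition table the
#' likelihood consumes.
#'
#' @param obs data frame with cell_id, a time column (`window_center_h` or
#'   `time_h`) and `damage_kBT` (optionally `valid`).
#' @return Data frame (cell_id, t0, x0, t1, x1), one row per consecutive
#'   valid observation pair within a cell.
#' @export
transition_table <- function(obs) {
  tcol <- intersect(c("window_center_h", "time_h"), names(obs))[1]
  if (is.na(tcol)) stop("no time column found", call. = FALSE)
  if ("valid" %in% names(obs)) obs <- obs[obs$valid, ]
  obs <- obs[is.finite(obs$damage_kBT), ]
  obs <- obs[order(obs$cell_id, obs[[tcol]]), ]
  by_cell <- split(obs, obs$cell_id)
  rows <- lapply(by_cell, function(d) {
    n <- nrow(d)
    if (n < 2L) return(NULL)
    data.frame(cell_id = d$cell_id[-n], t0 = d[[tcol]][-n],
               x0 = d$damage_kBT[-n], t1 = d[[tcol]][-1],
               x1 = d$damage_kBT[-1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit configuration for MP-SR maximum likelihood
#'
#' @param backend `"euler_gauss"` (fast Gaussian transition approximation
#'   with sub-stepped moment propagation; the desk-scale default) or
#'   `"sim_kde"` (the simulation-based likelihood: per transition, simulate
#'   the model and estimate the endpoint density by Gaussian kernel density —
#'   faithful but heavy).
#' @param sims_per_transition simulated paths per transition for `sim_kde`
#'   (>= 100; default 1000).
#' @param grid named list of `c(low, high)` search ranges for eta, beta,
#'   sigma, a, kappa, eta0. Defaults span the physiologically plausible box
#'   (production slope 1e-3..1e-2 kBT/h^2, removal 0.4..2 kBT/h, noise
#'   0.04..0.36 (kBT)^2/h, cooperativity 0.1..0.6 1/kBT, half-saturation
#'   -0.7..1.3 kBT, offset 0.05..0.75 kBT/h).
#' @param halving_factor range shrink factor applied when the optimum is
#'   interior (default 2).
#' @param max_iterations cap on search iterations (default 40).
#' @param sub_step_h internal Euler step for the Gaussian backend, hours
#'   (default 0.5).
#' @param sim_dt_h Euler-Maruyama step for `sim_kde` simulations (default
#'   0.05).
#' @param n_boot bootstrap replicates over cells for the log-likelihood
#'   difference CIs used in the convergence check (default 200).
#' @param n_boot_theta bootstrap refits for parameter CIs (default 0: off,
#'   as refitting is expensive; set e.g. 20 for CIs).
#' @param min_width named or scalar minimal half-widths at which a dimension
#'   stops shrinking (default 1/200 of the initial range).
#' @param seed RNG seed (controls sim_kde common random numbers and
#'   bootstraps).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(backend = c("euler_gauss", "sim_kde"),
                       sims_per_transition = 1000,
                       grid = NULL,
                       halving_factor = 2,
                       max_iterations = 40,
                       sub_step_h = 0.5,
                       sim_dt_h = 0.05,
                       n_boot = 200,
                       n_boot_theta = 0,
                       min_width = NULL,
                       seed = 1) {
  backend <- match.arg(backend)
  if (backend == "sim_kde" && sims_per_transition < 100)
    stop("sims_per_transition must be >= 100 for sim_kde", call. = FALSE)
  default_grid <- list(eta = c(1e-3, 1e-2), beta = c(0.4, 2),
                       sigma = c(0.04, 0.36), a = c(0.1, 0.6),
                       kappa = c(-0.7, 1.3), eta0 = c(0.05, 0.75))
  if (is.null(grid)) grid <- default_grid
  stopifnot(setequal(names(grid), names(default_grid)))
  for (nm in c("eta", "beta", "sigma", "a"))
    if (grid[[nm]][1] <= 0) stop(nm, " range must be positive", call. = FALSE)
  if (is.null(min_width))
    min_width <- vapply(grid, function(g) diff(g) / 200, numeric(1))
  structure(list(backend = backend,
                 sims_per_transition = sims_per_transition,
                 grid = grid, halving_factor = halving_factor,
                 max_iterations = max_iterations, sub_step_h = sub_step_h,
                 sim_dt_h = sim_dt_h, n_boot = n_boot,
                 n_boot_theta = n_boot_theta,
                 min_width = min_width, seed = seed),
            class = "fit_config")
}

theta_to_params <- function(th) {
  mpsr_params(eta0 = th[["eta0"]], eta = th[["eta"]], beta = th[["beta"]],
              sigma = th[["sigma"]], a = th[["a"]], kappa = th[["kappa"]])
}

#' Total transition log-likelihood of damage trajectories under the MP-SR model
#'
#' Sums `ln P[(t1, x1) | (t0, x0); theta]` over all observed transitions.
#' The `euler_gauss` backend propagates a Gaussian through the nonlinear
#' drift by sub-stepping: mean `m <- m + G(m, t) dt`, variance
#' `v <- v (1 + 2 G_x(m) dt) + 2 sigma dt` — exact for linear drift and
#' accurate when the relaxation rate times the observation gap is small. The
#' `sim_kde` backend simulates `sims_per_transition` Euler-Maruyama paths per
#' transition (with per-transition seeds derived from `config$seed`, i.e.
#' common random numbers across theta) and evaluates a Gaussian KDE with
#' Silverman bandwidth at the observed endpoint. Densities are floored at
#' 1e-300; the flooring count is attached as an attribute.
#'
#' @param transitions a [transition_table()] data frame.
#' @param theta an [mpsr_params()] object or named vector with eta0, eta,
#'   beta, sigma, a, kappa.
#' @param config a [fit_config()].
#' @return Total log-likelihood (scalar) with attributes `n_floored` and
#'   `per_transition` (vector of per-transition log-densities).
#' @export
transition_loglik <- function(transitions, theta, config = fit_config()) {
  if (is.null(transitions) || nrow(transitions) == 0L)
    stop("no transitions", call. = FALSE)
  if (inherits(theta, "mpsr_params")) theta <- unlist(theta)
  ll <- if (config$backend == "euler_gauss")
    loglik_euler_gauss(transitions, theta, config$sub_step_h)
  else
    loglik_sim_kde(transitions, theta, config)
  out <- sum(ll$logdens)
  attr(out, "n_floored") <- ll$n_floored
  attr(out, "per_transition") <- ll$logdens
  out
}

loglik_euler_gauss <- function(tr, th, sub_step_h) {
  thm <- rbind(th[c("eta", "beta", "sigma", "a", "kappa", "eta0")])
  colnames(thm) <- c("eta", "beta", "sigma", "a", "kappa", "eta0")
  ld <- attr(loglik_euler_gauss_grid(tr, thm, sub_step_h, per_transition = TRUE),
             "per_transition")
  floored <- ld <= base::log(1e-300) + 1e-9
  list(logdens = ld, n_floored = sum(floored))
}

# (e^x - 1)/x, stable near 0
phi_fun <- function(x) ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)

# grid-vectorized Gaussian backend: evaluates the log-likelihood for every
# row of a k x 6 theta matrix at once (transitions x thetas matrices), which
# is what makes the 3^6 factorial search affordable in pure R
loglik_euler_gauss_grid <- function(tr, thetas, sub_step_h,
                                    per_transition = FALSE) {
  n <- nrow(tr); k <- nrow(thetas)
  # bound peak memory: the propagation holds ~10 n x k matrices, so cap
  # n * k at ~4e6 entries and process the theta grid in chunks
  chunk <- max(1L, floor(4e6 / n))
  if (k > chunk) {
    idx <- split(seq_len(k), ceiling(seq_len(k) / chunk))
    return(unlist(lapply(idx, function(i)
      loglik_euler_gauss_grid(tr, thetas[i, , drop = FALSE], sub_step_h)),
      use.names = FALSE))
  }
  gap <- tr$t1 - tr$t0
  n_sub <- max(1L, ceiling(max(gap) / sub_step_h))
  dt <- matrix(gap / n_sub, n, k)
  a_m <- matrix(thetas[, "a"], n, k, byrow = TRUE)
  kap_m <- matrix(thetas[, "kappa"], n, k, byrow = TRUE)
  beta_m <- matrix(thetas[, "beta"], n, k, byrow = TRUE)
  eta_m <- matrix(thetas[, "eta"], n, k, byrow = TRUE)
  eta0_m <- matrix(thetas[, "eta0"], n, k, byrow = TRUE)
  sig2dt <- matrix(2 * thetas[, "sigma"], n, k, byrow = TRUE) * dt
  m <- matrix(tr$x0, n, k)
  v <- matrix(0, n, k)
  tt <- matrix(tr$t0, n, k)
  # midpoint (RK2) mean propagation with the exact Ornstein-Uhlenbeck
  # variance update for the midpoint-frozen relaxation rate: the systematic
  # per-transition bias of plain Euler moments, though tiny, adds up over
  # 10^4 transitions and visibly tilts the likelihood surface
  for (s in seq_len(n_sub)) {
    f1 <- stats::plogis(a_m * (m - kap_m))
    g1 <- eta0_m + eta_m * tt - beta_m * f1
    m2 <- m + g1 * (dt / 2)
    f2 <- stats::plogis(a_m * (m2 - kap_m))
    g2 <- eta0_m + eta_m * (tt + dt / 2) - beta_m * f2
    gx2 <- -beta_m * a_m * f2 * (1 - f2)
    e <- exp(2 * gx2 * dt)
    v <- v * e + sig2dt * phi_fun(2 * gx2 * dt)
    m <- m + g2 * dt
    tt <- tt + dt
  }
  v <- pmax(v, 1e-12)
  ld <- pmax(-0.5 * (base::log(2 * pi * v) + (tr$x1 - m)^2 / v),
             base::log(1e-300))
  out <- colSums(ld)
  if (per_transition) attr(out, "per_transition") <- ld[, 1]
  out
}

loglik_sim_kde <- function(tr, th, config) {
  nsim <- config$sims_per_transition
  dt <- config$sim_dt_h
  logdens <- numeric(nrow(tr))
  n_floored <- 0L
  eta0 <- th[["eta0"]]; eta <- th[["eta"]]; beta <- th[["beta"]]
  sigma <- th[["sigma"]]; a <- th[["a"]]; kappa <- th[["kappa"]]
  for (i in seq_len(nrow(tr))) {
    gap <- tr$t1[i] - tr$t0[i]
    n_steps <- max(1L, round(gap / dt))
    dti <- gap / n_steps
    # common random numbers: the i-th transition always uses the same draws,
    # whatever theta, so likelihood comparisons across theta are smooth
    set.seed(cell_seed(config$seed, i))
    z <- matrix(stats::rnorm(nsim * n_steps), nsim, n_steps)
    x <- rep(tr$x0[i], nsim)
    tt <- tr$t0[i]
    for (k in seq_len(n_steps)) {
      f <- stats::plogis(a * (x - kappa))
      x <- x + (eta0 + eta * tt - beta * f) * dti +
        sqrt(2 * sigma * dti) * z[, k]
      tt <- tt + dti
    }
    bw <- stats::bw.nrd0(x)
    d <- mean(stats::dnorm(tr$x1[i], x, bw))
    if (d < 1e-300) { d <- 1e-300; n_floored <- n_floored + 1L }
    logdens[i] <- base::log(d)
  }
  list(logdens = logdens, n_floored = n_floored)
}

#' Maximum-likelihood fit of the MP-SR parameters
#'
#' Iterative interval-halving grid search over the six-dimensional parameter
#' space: each iteration evaluates the transition log-likelihood on the full
#' 3^6 factorial grid (low, centre, high per dimension), moves the centre to
#' the best point, and halves the half-width of every dimension in which the
#' best point was interior. Convergence requires (1) the optimum interior in
#' all dimensions and (2) the log-likelihood differences between the optimum
#' and its 12 axis neighbours to lie within their cell-bootstrap confidence
#' intervals. Cells are exchangeable: the likelihood is a sum over
#' transitions, so permuting cells leaves the fit unchanged.
#'
#' @param transitions a [transition_table()] data frame (or a windows data
#'   frame, which is converted).
#' @param config a [fit_config()].
#' @param verbose print per-iteration progress.
#' @return A list of class `mpsr_fit`: `theta_hat` (`mpsr_params`), `loglik`,
#'   `iterations`, `converged`, `boundary` (names of dimensions pinned at the
#'   search bounds, if any), `n_transitions`, `n_cells`, `ll_diff_ci` (table
#'   of neighbour log-likelihood differences and their CIs), `theta_ci`
#'   (bootstrap parameter CIs when `config$n_boot_theta > 0`), `config`.
#' @export
fit_mpsr <- function(transitions, config = fit_config(), verbose = FALSE) {
  if (!all(c("t0", "x0", "t1", "x1") %in% names(transitions)))
    transitions <- transition_table(transitions)
  par_names <- c("eta", "beta", "sigma", "a", "kappa", "eta0")
  lo <- vapply(config$grid, `[`, numeric(1), 1)[par_names]
  hi <- vapply(config$grid, `[`, numeric(1), 2)[par_names]
  centre <- (lo + hi) / 2
  width <- (hi - lo) / 2
  min_w <- if (length(config$min_width) == 1L)
    rep(config$min_width, 6) else config$min_width[par_names]
  positive <- c(eta = TRUE, beta = TRUE, sigma = TRUE, a = TRUE,
                kappa = FALSE, eta0 = TRUE)
  ll_at <- function(th) {
    names(th) <- par_names
    as.numeric(transition_loglik(transitions, th, config))
  }
  offsets <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 6)))
  colnames(offsets) <- par_names
  init_width <- width
  best_ever <- NULL
  iter <- 0L
  interior <- FALSE
  ll_within_ci <- FALSE
  repeat {
    iter <- iter + 1L
    cand <- sweep(offsets, 2, width, `*`)
    cand <- sweep(cand, 2, centre, `+`)
    # keep strictly positive parameters positive and inside the search box
    for (j in seq_len(6)) {
      lb <- if (positive[j]) max(lo[j] / 4, 1e-8) else lo[j] - width[j] * 2
      cand[, j] <- pmin(pmax(cand[, j], lb), hi[j] + width[j] * 2)
    }
    lls <- if (config$backend == "euler_gauss")
      loglik_euler_gauss_grid(transitions, cand, config$sub_step_h)
    else apply(cand, 1, ll_at)
    k <- which.max(lls)
    if (is.null(best_ever) || lls[k] > best_ever$ll)
      best_ever <- list(theta = cand[k, ], ll = lls[k])
    interior <- all(offsets[k, ] == 0)
    if (verbose)
      message(sprintf("iter %2d  ll=%.2f  interior=%s  width=%s", iter,
                      lls[k], interior,
                      paste(signif(width, 2), collapse = "/")))
    if (interior) {
      shrink <- width / config$halving_factor
      width <- pmax(shrink, min_w)
      at_floor <- all(shrink <= min_w)
      refined <- all(width <= init_width / 16)
      # the statistical stopping rule only applies once the grid is fine
      # enough that remaining moves are within the flat top of the surface
      if (refined || at_floor || iter >= config$max_iterations) {
        ci <- ll_diff_ci(transitions, centre, width, par_names, config)
        ll_within_ci <- all(ci$within)
        if (ll_within_ci || at_floor || iter >= config$max_iterations) break
      }
    } else {
      centre <- cand[k, ]
      if (iter >= config$max_iterations) {
        ci <- ll_diff_ci(transitions, centre, width, par_names, config)
        ll_within_ci <- all(ci$within)
        break
      }
    }
  }
  theta_hat <- best_ever$theta
  names(theta_hat) <- par_names
  on_boundary <- par_names[theta_hat <= lo + 1e-12 | theta_hat >= hi - 1e-12]
  n_cells <- length(unique(transitions$cell_id))
  theta_ci <- NULL
  if (config$n_boot_theta > 0)
    theta_ci <- boot_theta_ci(transitions, config)
  structure(list(theta_hat = theta_to_params(theta_hat),
                 loglik = best_ever$ll,
                 iterations = iter,
                 converged = interior && ll_within_ci &&
                   length(on_boundary) == 0L,
                 boundary = on_boundary,
                 n_transitions = nrow(transitions),
                 n_cells = n_cells,
                 ll_diff_ci = ci,
                 theta_ci = theta_ci,
                 config = config),
            class = "mpsr_fit")
}

# bootstrap (over cells) CIs of the log-likelihood differences between the
# current optimum and its 12 axis neighbours: when every difference is within
# its CI, the remaining grid structure is statistically unresolvable
ll_diff_ci <- function(transitions, centre, width, par_names, config) {
  per_t <- function(th) {
    names(th) <- par_names
    attr(transition_loglik(transitions, th, config), "per_transition")
  }
  base_ll <- per_t(centre)
  cells <- transitions$cell_id
  ucells <- unique(cells)
  rows <- list()
  for (j in seq_along(par_names)) {
    for (s in c(-1, 1)) {
      th <- centre
      th[j] <- th[j] + s * width[j]
      if (par_names[j] != "kappa" && th[j] <= 0) th[j] <- centre[j] / 2
      nb_ll <- per_t(th)
      diff_t <- base_ll - nb_ll
      # cell-level sums, resampled
      cell_sum <- tapply(diff_t, cells, sum)
      set.seed(cell_seed(config$seed, 1000 + 2 * j + (s + 1) / 2))
      reps <- vapply(seq_len(config$n_boot), function(b)
        sum(cell_sum[sample.int(length(ucells), length(ucells),
                                replace = TRUE)]),
        numeric(1))
      ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par_names[j], side = s, ll_diff = sum(diff_t),
        ci_low = ci[1], ci_high = ci[2],
        within = ci[1] <= 0)
    }
  }
  do.call(rbind, rows)
}

boot_theta_ci <- function(transitions, config) {
  cells <- unique(transitions$cell_id)
  n <- length(cells)
  sub_cfg <- config
  sub_cfg$n_boot_theta <- 0
  sub_cfg$max_iterations <- max(10L, config$max_iterations %/% 2L)
  reps <- matrix(NA_real_, config$n_boot_theta, 6)
  colnames(reps) <- c("eta", "beta", "sigma", "a", "kappa", "eta0")
  for (b in seq_len(config$n_boot_theta)) {
    set.seed(cell_seed(config$seed, 5000 + b))
    pick <- sample(cells, n, replace = TRUE)
    tr_b <- do.call(rbind, lapply(seq_along(pick), function(i) {
      d <- transitions[transitions$cell_id == pick[i], ]
      d$cell_id <- paste0("boot_", i)
      d
    }))
    fit_b <- fit_mpsr(tr_b, sub_cfg)
    reps[b, ] <- unlist(fit_b$theta_hat)[c("eta", "beta", "sigma", "a",
                                           "kappa", "eta0")]
  }
  apply(reps, 2, stats::quantile, probs = c(0.025, 0.975))
}

#' @export
print.mpsr_fit <- function(x, ...) {
  cat(sprintf("MP-SR maximum-likelihood fit (%s backend)\n",
              x$config$backend))
  cat(sprintf("  %d transitions from %d cells; loglik %.2f; %d iterations; %s\n",
              x$n_transitions, x$n_cells, x$loglik, x$iterations,
              if (x$converged) "converged" else
                paste0("NOT converged",
                       if (length(x$boundary))
                         paste0(" (boundary: ",
                                paste(x$boundary, collapse = ", "), ")")
                       else "")))
  print(x$theta_hat)
  invisible(x)
}

#' Write a fit result to JSON
#'
#' @param fit an `mpsr_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  p <- fit$theta_hat
  jsonlite::write_json(list(
    theta_hat = list(eta0 = p$eta0, eta = p$eta, beta = p$beta,
                     sigma = p$sigma, a = p$a, kappa = p$kappa),
    loglik = fit$loglik, iterations = fit$iterations,
    converged = fit$converged, boundary = fit$boundary,
    n_transitions = fit$n_transitions, n_cells = fit$n_cells,
    backend = fit$config$backend, seed = fit$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
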