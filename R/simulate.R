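#' Simulate MP-SR damage trajectories
#'
#' Euler-Maruyama integration of the MP-SR stochastic differential equation
#' \eqn{dX = (\eta_0 + \eta t - \beta f(X))\,dt + \sqrt{2\sigma}\,dW} on a
#' uniform grid. Each cell consumes its own RNG stream derived from the master
#' seed, so results for cell i do not depend on how many cells are simulated.
#'
#' @param params an [mpsr_params()] object.
#' @param x0_sampler initial damage: a single number (point mass), a numeric
#'   vector of length `n`, or a function `function(n, seed)` returning `n`
#'   draws. Default: draws from the quasi-steady-state density at `t0` (see
#'   [qss_sampler()]).
#' @param t0,t1 start and end age, hours; `t1 > t0`.
#' @param dt integration step, hours; must be < 1 (default 0.05).
#' @param n number of cells.
#' @param seed master integer seed.
#' @param rule optional [death_rule()]; when supplied, paths are absorbed
#'   (set to `NA`) after first crossing `x_c` and crossing times recorded.
#' @param drift_offset per-cell additive production offset, kBT/h (scalar or
#'   length `n`); models stable cell-to-cell differences in damage production
#'   on top of the shared parameters. Default 0.
#' @return A list of class `trajectory_ensemble` with `times` (grid, length m),
#'   `paths` (n x m matrix of damage X; `NA` after absorption), `params`,
#'   `dt`, `seed`, and — when `rule` is given — `death_times` (linearly
#'   interpolated first-passage ages, `NA` if not absorbed) and `rule`.
#' @export
simulate_paths <- function(params, x0_sampler = NULL, t0 = 20, t1 = 80,
                           dt = 0.05, n = 100, seed = 1, rule = NULL,
                           drift_offset = 0) {
  stopifnot(inherits(params, "mpsr_params"))
  if (t1 <= t0) stop("t1 must exceed t0", call. = FALSE)
  if (dt <= 0 || dt >= 1)
    stop("dt must be in (0, 1) h (coarser steps are rejected)", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  times <- seq(t0, t1, by = dt)
  m <- length(times)
  x0 <- resolve_x0(x0_sampler, n, params, t0, seed)
  if (!length(drift_offset) %in% c(1L, n) || !all(is.finite(drift_offset)))
    stop("drift_offset must be finite, length 1 or n", call. = FALSE)
  offs <- rep_len(drift_offset, n)
  x_c <- if (!is.null(rule)) rule$x_c else Inf
  # per-cell increment streams: cell i's draws depend only on (seed, i), so
  # enlarging n leaves earlier cells' paths unchanged
  z <- matrix(NA_real_, n, m - 1L)
  for (i in seq_len(n)) {
    set.seed(cell_seed(seed, i))
    z[i, ] <- stats::rnorm(m - 1L)
  }
  paths <- matrix(NA_real_, n, m)
  death_times <- rep(NA_real_, n)
  paths[, 1] <- x0
  x <- x0
  alive <- rep(TRUE, n)
  noise_sd <- sqrt(2 * params$sigma * dt)
  for (k in seq_len(m - 1L)) {
    if (!any(alive)) break
    g <- params$eta0 + offs[alive] + params$eta * times[k] -
      params$beta * stats::plogis(params$a * (x[alive] - params$kappa))
    x_new <- x[alive] + g * dt + noise_sd * z[alive, k]
    crossed <- x_new >= x_c
    if (any(crossed)) {
      idx <- which(alive)[crossed]
      # linear interpolation of the crossing age within the step
      frac <- (x_c - x[idx]) / (x_new[crossed] - x[idx])
      death_times[idx] <- times[k] + frac * dt
      x_new[crossed] <- x_c
    }
    x[alive] <- x_new
    paths[alive, k + 1L] <- x_new
    if (any(crossed)) alive[which(alive)[crossed]] <- FALSE
  }
  out <- list(times = times, paths = paths, params = params, dt = dt,
              seed = seed)
  if (!is.null(rule)) {
    out$rule <- rule
    out$death_times <- death_times
  }
  structure(out, class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("MP-SR trajectory ensemble: %d cells on [%g, %g] h (dt = %g)\n",
              nrow(x$paths), min(x$times), max(x$times), x$dt))
  if (!is.null(x$death_times))
    cat(sprintf("  absorbed at x_c = %g: %d of %d cells\n", x$rule$x_c,
                sum(!is.na(x$death_times)), nrow(x$paths)))
  invisible(x)
}

# deterministic per-cell seed derived from the master seed; keeps the i-th
# cell's path identical regardless of n
cell_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

resolve_x0 <- function(x0_sampler, n, params, t0, seed) {
  if (is.null(x0_sampler)) x0_sampler <- qss_sampler(t0, params)
  if (is.function(x0_sampler)) {
    x0 <- x0_sampler(n, cell_seed(seed, 0L))
  } else if (length(x0_sampler) == 1L) {
    x0 <- rep(as.numeric(x0_sampler), n)
  } else {
    if (length(x0_sampler) != n)
      stop("x0_sampler vector must have length n", call. = FALSE)
    x0 <- as.numeric(x0_sampler)
  }
  if (!all(is.finite(x0))) stop("initial damage must be finite", call. = FALSE)
  x0
}

#' Sampler for the quasi-steady-state damage density
#'
#' Returns a function drawing initial damage values from the Boltzmann
#' quasi-steady density at age `t0` by inverse-CDF sampling on a fine grid.
#'
#' @param t0 age, hours.
#' @param params an [mpsr_params()] object.
#' @return A function `function(n, seed)`.
#' @export
qss_sampler <- function(t0, params) {
  q <- qss_density(t0, params)
  dx <- diff(q$x)
  cdf <- cumsum(c(0, (q$density[-1] + q$density[-length(q$density)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  xs <- q$x[keep]; cdf <- cdf[keep]
  function(n, seed) {
    set.seed(seed)
    stats::approx(cdf, xs, xout = stats::runif(n), rule = 2)$y
  }
}

#' Sample first-passage death times of the MP-SR model
#'
#' Simulates `n` absorbed trajectories and returns the first-passage ages at
#' which damage crosses the death threshold, with linear interpolation within
#' the crossing step. Cells not absorbed by `horizon` are counted as censored,
#' never dropped.
#'
#' @inheritParams simulate_paths
#' @param rule a [death_rule()].
#' @param horizon end of simulation, hours.
#' @return A list of class `first_passage_sample` with `death_times` (sorted
#'   ages of absorbed cells), `censored` (count), `horizon`, `rule`, `n`,
#'   and `warning` (non-`NULL` when zero cells were absorbed).
#' @export
sample_first_passage <- function(params, rule, x0_sampler = NULL, t0 = 20,
                                 horizon = 120, dt = 0.05, n = 100, seed = 1) {
  ens <- simulate_paths(params, x0_sampler, t0, horizon, dt, n, seed,
                        rule = rule)
  dtimes <- ens$death_times[!is.na(ens$death_times)]
  warn <- NULL
  if (length(dtimes) == 0L) {
    warn <- "zero cells absorbed within horizon; hazard estimation will refuse"
    warning(warn, call. = FALSE)
  }
  structure(list(death_times = sort(dtimes),
                 censored = sum(is.na(ens$death_times)),
                 horizon = horizon, rule = rule, n = n, t0 = t0,
                 seed = seed, warning = warn),
            class = "first_passage_sample")
}

#' @export
print.first_passage_sample <- function(x, ...) {
  cat(sprintf(
    "First-passage sample: %d deaths, %d censored at %g h (x_c = %g)\n",
    length(x$death_times), x$censored, x$horizon, x$rule$x_c))
  if (length(x$death_times))
    cat(sprintf("  mean death time %.1f h\n", mean(x$death_times)))
  invisible(x)
}

#' Empirical hazard from a first-passage sample
#'
#' Nelson-Aalen-style hazard increments on fixed-width age bins:
#' (deaths in bin) / (cells at risk at bin start) / (bin width).
#'
#' @param fps a [sample_first_passage()] result.
#' @param bin_h bin width, hours (default 1).
#' @return A data frame with `age_h` (bin midpoints), `hazard` (per hour),
#'   `deaths`, `at_risk`.
#' @export
empirical_hazard <- function(fps, bin_h = 1) {
  stopifnot(inherits(fps, "first_passage_sample"))
  if (length(fps$death_times) == 0L)
    stop("no deaths in sample; cannot estimate a hazard", call. = FALSE)
  breaks <- seq(fps$t0, fps$horizon + bin_h, by = bin_h)
  deaths <- as.integer(table(cut(fps$death_times, breaks, right = FALSE)))
  at_risk <- fps$n - c(0, cumsum(deaths))[seq_along(deaths)]
  data.frame(age_h = breaks[-length(breaks)] + bin_h / 2,
             hazard = ifelse(at_risk > 0, deaths / at_risk / bin_h, NA_real_),
             deaths = deaths, at_risk = at_risk)
}

#' Analytic escape-rate hazard of the MP-SR model
#'
#' Instantaneous death rate at age `t` for the frozen-age potential, treating
#' death as diffusive escape from the potential well across the absorbing
#' threshold `x_c`. Because the MP-SR potential is strictly convex (removal is
#' monotone in damage), there is no interior barrier top; the escape barrier
#' is the potential difference up to the threshold itself,
#' \eqn{\Delta U(t) = U(x_c,t) - U(x_{min},t)}, which shrinks roughly linearly
#' with age — hence a hazard rising exponentially with age (Gompertz law).
#'
#' Two estimators are provided:
#' \describe{
#'   \item{`"mfpt"`}{(default) reciprocal of the exact frozen-potential mean
#'     first-passage time from the well minimum to `x_c`,
#'     \eqn{T = \sigma^{-1}\int_{x_{min}}^{x_c} e^{U(y)/\sigma}
#'       \int_{-\infty}^{y} e^{-U(z)/\sigma} dz\, dy}, by quadrature.}
#'   \item{`"saddle"`}{Laplace approximation of the same integral,
#'     \eqn{h = U'(x_c)\sqrt{U''(x_{min})/(2\pi\sigma)}\;
#'       e^{-\Delta U/\sigma}}, exposing the exponential-in-barrier form.}
#' }
#'
#' @param params an [mpsr_params()] object.
#' @param rule a [death_rule()].
#' @param t age(s), hours.
#' @param method `"mfpt"` or `"saddle"`.
#' @return Hazard(s) in 1/h, one per element of `t`.
#' @export
kramers_hazard <- function(params, rule, t, method = c("mfpt", "saddle")) {
  method <- match.arg(method)
  vapply(t, function(tt) kramers_hazard_1(params, rule, tt, method),
         numeric(1))
}

kramers_hazard_1 <- function(params, rule, t, method) {
  if (!is_confining(t, params) ||
      (params$eta0 + params$eta * t) <= 0)
    stop(structure(class = c("mpsr_no_barrier", "error", "condition"),
                   list(message = sprintf(
                     "beyond the escape-rate regime at t = %g h: no confining interior minimum",
                     t), call = sys.call(-1))))
  x_min <- qss_mode(t, params)
  if (x_min >= rule$x_c)
    stop(structure(class = c("mpsr_no_barrier", "error", "condition"),
                   list(message = sprintf(
                     "beyond the escape-rate regime at t = %g h: well minimum %.3g >= x_c = %g",
                     t, x_min, rule$x_c), call = sys.call(-1))))
  sig <- params$sigma
  U <- function(x) mpsr_potential(x, t, params)
  if (method == "saddle") {
    dU  <- U(rule$x_c) - U(x_min)
    upp <- -mpsr_drift_dx(x_min, params)  # U'' = -G'
    uprime_c <- -mpsr_drift(rule$x_c, t, params)
    return(uprime_c * sqrt(upp / (2 * pi * sig)) * exp(-dU / sig))
  }
  # exact MFPT by nested quadrature on a grid from deep in the well to x_c
  sd0 <- sqrt(sig / (-mpsr_drift_dx(x_min, params)))
  lo <- x_min - 12 * sd0
  xg <- seq(lo, rule$x_c, length.out = 4000L)
  u <- U(xg)
  u <- u - min(u)
  inner <- cumsum(c(0, diff(xg) * (exp(-u[-1] / sig) +
                                     exp(-u[-length(u)] / sig)) / 2))
  integrand <- exp(pmin(u / sig, 700)) * inner
  keep <- xg >= x_min
  mfpt <- trapz(xg[keep], integrand[keep]) / sig
  1 / mfpt
}
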