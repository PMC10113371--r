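#' Saturating removal fraction f(X)
#'
#' The fraction of maximal damage-removal capacity engaged at damage level
#' `x`: \deqn{f(X) = \frac{e^{aX}}{e^{aX} + e^{a\kappa}},}
#' a two-state partition function sensing the loss of membrane potential.
#' Strictly increasing in `x`, bounded in (0, 1), and equal to 1/2 at
#' `x = kappa`.
#'
#' @param x damage level(s), kBT; must be finite.
#' @param params an [mpsr_params()] object.
#' @return Removal fraction(s) in (0, 1), same length as `x`.
#' @export
removal_fraction <- function(x, params) {
  stopifnot(inherits(params, "mpsr_params"))
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  # logistic in a*(x - kappa); plogis is overflow-safe for large |x|
  stats::plogis(params$a * (x - params$kappa))
}

#' Drift (deterministic rate of change) of damage
#'
#' Production minus removal at damage `x` and age `t`:
#' `eta0 + eta * t - beta * removal_fraction(x)`, in kBT/h.
#'
#' @param x damage level(s), kBT.
#' @param t age(s), hours; must be >= 0. Recycled against `x`.
#' @param params an [mpsr_params()] object.
#' @return Drift value(s), kBT/h.
#' @export
mpsr_drift <- function(x, t, params) {
  if (any(t < 0)) stop("age t must be >= 0", call. = FALSE)
  params$eta0 + params$eta * t - params$beta * removal_fraction(x, params)
}

# derivative of drift w.r.t. x (used by the Gaussian transition backend and
# by curvature-based escape rates): d/dx [-beta f(x)] = -beta a f (1 - f)
mpsr_drift_dx <- function(x, params) {
  f <- removal_fraction(x, params)
  -params$beta * params$a * f * (1 - f)
}

#' Confinement check for the quasi-steady state
#'
#' The frozen-age potential is confining (the quasi-steady density
#' normalizable) iff production at age `t` is below the maximal removal rate:
#' `eta0 + eta * t < beta`.
#'
#' @param t age(s), hours.
#' @param params an [mpsr_params()] object.
#' @return Logical vector.
#' @export
is_confining <- function(t, params) {
  params$eta0 + params$eta * t < params$beta
}

#' Frozen-age potential U(X, t)
#'
#' The potential whose gradient is minus the drift,
#' \deqn{U(X,t) = \beta/a \, \ln(e^{a\kappa} + e^{aX}) - (\eta_0+\eta t) X + C,}
#' in (kBT)^2. The additive constant is fixed by `U(kappa, t) = 0` so that
#' serialized potentials are reproducible.
#'
#' @param x damage value(s), kBT.
#' @param t age, hours (scalar).
#' @param params an [mpsr_params()] object.
#' @return Potential value(s), (kBT)^2.
#' @export
mpsr_potential <- function(x, t, params) {
  if (length(t) != 1L || t < 0) stop("t must be a single age >= 0",
                                     call. = FALSE)
  prod_rate <- params$eta0 + params$eta * t
  a <- params$a; kap <- params$kappa
  # log(e^{a kappa} + e^{a x}) computed stably via the larger exponent
  lse  <- function(x) a * pmax(x, kap) + log1p(exp(-a * abs(x - kap)))
  u    <- params$beta / a * lse(x) - prod_rate * x
  u0   <- params$beta / a * (a * kap + log(2)) - prod_rate * kap
  u - u0
}

#' Quasi-steady-state potential and damage density at a fixed age
#'
#' Under timescale separation the damage distribution at age `t` is the
#' Boltzmann form \eqn{P(X) \propto e^{-U(X,t)/\sigma}}. This evaluates the
#' potential on `x_grid` and returns the density normalized to integrate to 1
#' over the grid by the trapezoid rule. Requires the confining regime
#' `eta0 + eta*t < beta`; otherwise no quasi-steady state exists and an error
#' of class `mpsr_no_qss` is signalled.
#'
#' @param t age, hours (scalar).
#' @param params an [mpsr_params()] object.
#' @param x_grid strictly increasing damage values covering the bulk of the
#'   density mass; default an automatic grid around the drift fixed point.
#' @return A list with `x` (the grid), `U` (potential, zeroed at `x = kappa`),
#'   `density` (normalized), and `x_star` (the interior drift fixed point).
#' @export
qss_density <- function(t, params, x_grid = NULL) {
  stopifnot(inherits(params, "mpsr_params"))
  if (!is_confining(t, params))
    stop(structure(class = c("mpsr_no_qss", "error", "condition"),
                   list(message = sprintf(
                     paste0("no quasi-steady state at t = %g h: production ",
                            "eta0 + eta*t = %g >= beta = %g (non-confining ",
                            "potential)"),
                     t, params$eta0 + params$eta * t, params$beta),
                     call = sys.call(-1))))
  x_star <- qss_mode(t, params)
  if (is.null(x_grid)) {
    sd0 <- sqrt(params$sigma / (-mpsr_drift_dx(x_star, params)))
    x_grid <- seq(x_star - 10 * sd0, x_star + 10 * sd0, length.out = 2001L)
  }
  if (is.unsorted(x_grid, strictly = TRUE))
    stop("x_grid must be strictly increasing", call. = FALSE)
  u <- mpsr_potential(x_grid, t, params)
  w <- exp(-(u - min(u)) / params$sigma)
  dens <- w / trapz(x_grid, w)
  list(x = x_grid, U = u, density = dens, x_star = x_star)
}

# interior fixed point of the drift: f(x*) = (eta0 + eta t)/beta, solved in
# closed form from the logistic removal fraction
qss_mode <- function(t, params) {
  frac <- (params$eta0 + params$eta * t) / params$beta
  if (frac <= 0 || frac >= 1)
    stop("no interior fixed point: production/beta outside (0, 1)",
         call. = FALSE)
  params$kappa + stats::qlogis(frac) / params$a
}

# trapezoid-rule integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
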