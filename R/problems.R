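#' Bimodal run-time-skewed test problem
#'
#' One-parameter model `y = theta^2 + noise` with a uniform prior on
#' `[-B, B]` and observation `y_obs = 1`, so the posterior is bimodal with
#' modes near `theta = +/-1`. Declared simulation durations are artificially
#' skewed by mode: simulations with `theta > 0` draw a log-normal duration,
#' while `theta <= 0` takes a short constant time. The duration law depends
#' only on the sign of `theta`, which makes the problem a sharp probe for
#' run-time bias: any scheduler whose acceptance effectively depends on
#' finish order under-represents the slow (positive) mode.
#'
#' @param B Prior half-width (default 2).
#' @param noise_sd Gaussian observation noise sd (default 0.1).
#' @param meanlog,sdlog2 Parameters of the log-normal duration for
#'   `theta > 0`: mean and *variance* of `log(duration)` (defaults 1 and 2).
#' @param fast_duration Constant duration in simulated seconds for
#'   `theta <= 0` (default 0.1).
#' @param y_obs Observed value (default 1).
#' @return An [abc_problem].
#' @export
problem_t1 <- function(B = 2, noise_sd = 0.1, meanlog = 1, sdlog2 = 2,
                       fast_duration = 0.1, y_obs = 1) {
  stopifnot(B > 0, noise_sd >= 0, sdlog2 > 0, fast_duration >= 0)
  sdlog <- sqrt(sdlog2)
  abc_problem(
    prior = uniform_prior(-B, B),
    model = function(theta) theta[1L]^2 + stats::rnorm(1L, 0, noise_sd),
    duration = function(theta) {
      if (theta[1L] > 0) stats::rlnorm(1L, meanlog, sdlog) else fast_duration
    },
    distance = function(y, y_obs) abs(y - y_obs),
    observed = y_obs,
    n_theta = 1L,
    name = "t1")
}

#' Conversion-reaction ODE test problem
#'
#' Two-parameter conversion reaction `x1 <-> x2` with forward rate `k1` and
#' backward rate `k2`, initial condition `x1(0) = 1, x2(0) = 0`, solved in
#' closed form:
#' `x2(t) = k1 / (k1 + k2) * (1 - exp(-(k1 + k2) t))`, `x1 = 1 - x2`
#' (mass conservation `x1 + x2 = 1`). Both species are observed on a fixed
#' time grid under multiplicative log-normal noise. Declared durations are a
#' parameter-independent log-normal "sleep" time of configurable log-scale
#' variance, emulating heterogeneous simulation run-times.
#'
#' Observed data are generated once, at problem construction, from the true
#' parameters under `obs_seed` (synthetic self-consistent data).
#'
#' @param k1_true,k2_true True rates used to generate the observed data
#'   (defaults 0.06 and 0.08).
#' @param times Output time grid (default 10 points on (0, 30]).
#' @param noise_sd Log-scale sd of the multiplicative noise (default 0.02).
#' @param sleep_sdlog2 Variance of `log(t_sleep)` (default 1; the
#'   run-time-heterogeneity scenarios use 1, 2 or 4).
#' @param sleep_meanlog Mean of `log(t_sleep)` (default 0).
#' @param prior_upper Upper bound of the uniform prior on each rate
#'   (default 0.5; lower bound 0).
#' @param obs_seed Seed for the one-off synthetic observation.
#' @return An [abc_problem] with an extra `trajectory(theta)` closure giving
#'   the noise-free solution (used by tests).
#' @export
problem_t2 <- function(k1_true = 0.06, k2_true = 0.08,
                       times = seq(3, 30, length.out = 10),
                       noise_sd = 0.02, sleep_sdlog2 = 1, sleep_meanlog = 0,
                       prior_upper = 0.5, obs_seed = 1L) {
  stopifnot(k1_true >= 0, k2_true >= 0, all(times > 0), noise_sd >= 0,
            sleep_sdlog2 > 0, prior_upper > 0)
  traj <- function(theta) {
    k1 <- theta[1L]; k2 <- theta[2L]
    if (k1 < 0 || k2 < 0) stop("reaction rates must be >= 0")
    s <- k1 + k2
    x2 <- if (s == 0) rep(0, length(times)) else k1 / s * (1 - exp(-s * times))
    c(1 - x2, x2)  # concatenated (x1, x2) on the grid
  }
  sdlog <- sqrt(sleep_sdlog2)
  y_obs <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_seed(old), add = TRUE)
    set.seed(obs_seed)
    traj(c(k1_true, k2_true)) * exp(stats::rnorm(2L * length(times), 0, noise_sd))
  })
  pr <- abc_problem(
    prior = uniform_prior(c(0, 0), c(prior_upper, prior_upper)),
    model = function(theta)
      traj(theta) * exp(stats::rnorm(2L * length(times), 0, noise_sd)),
    duration = function(theta) stats::rlnorm(1L, sleep_meanlog, sdlog),
    distance = function(y, y_obs) sqrt(sum((y - y_obs)^2)),
    observed = y_obs,
    n_theta = 2L,
    name = "t2")
  pr$trajectory <- traj
  pr
}

#' Gaussian toy problem with an exact quadrature oracle
#'
#' Conjugate-style toy: prior `theta ~ N(0, tau^2)`, model `y ~ N(theta, 1)`,
#' scalar observation, distance `|y - y_obs|`. Its uniform-kernel ABC
#' posterior at threshold `epsilon` has density proportional to
#' `dnorm(theta, 0, tau) * (pnorm(y_obs + eps - theta) - pnorm(y_obs - eps - theta))`,
#' so posterior summaries are available by quadrature to high accuracy,
#' giving an independent correctness oracle for the samplers. Declared
#' durations are log-normal by default (so scheduling paths with stragglers
#' are exercised) or a constant.
#'
#' @param tau Prior sd (default 1).
#' @param y_obs Scalar observation (default 1).
#' @param dur_sdlog Log-sd of the log-normal duration; `0` gives constant
#'   durations `dur_const`.
#' @param dur_const Constant duration used when `dur_sdlog = 0` (default 1).
#' @return An [abc_problem].
#' @export
problem_gauss <- function(tau = 1, y_obs = 1, dur_sdlog = 1, dur_const = 1) {
  stopifnot(tau > 0, dur_sdlog >= 0, dur_const > 0)
  pr <- abc_problem(
    prior = normal_prior(0, tau),
    model = function(theta) theta[1L] + stats::rnorm(1L),
    duration = if (dur_sdlog > 0) {
      function(theta) stats::rlnorm(1L, 0, dur_sdlog)
    } else {
      function(theta) dur_const
    },
    distance = function(y, y_obs) abs(y - y_obs),
    observed = y_obs,
    n_theta = 1L,
    name = "gauss")
  pr$tau <- tau
  pr
}

#' Quadrature oracle for the Gaussian toy ABC posterior
#'
#' Mean (or an arbitrary moment) of the uniform-kernel ABC posterior of
#' [problem_gauss()] at threshold `epsilon`, computed by adaptive
#' quadrature. Used to validate sampler output; never used by the samplers.
#'
#' @param problem A [problem_gauss()] object (fields `prior`, `observed`).
#' @param epsilon Acceptance threshold, `> 0`.
#' @param f Integrand statistic (default identity, giving the mean).
#' @return Scalar expectation under the ABC posterior.
#' @export
oracle_posterior_mean <- function(problem, epsilon, f = identity) {
  stopifnot(epsilon > 0)
  tau <- problem$tau
  if (is.null(tau)) stop("problem does not carry a prior sd (not a gauss toy?)")
  y <- problem$observed
  kern <- function(th)
    stats::dnorm(th, 0, tau) * (stats::pnorm(y + epsilon - th) -
                                stats::pnorm(y - epsilon - th))
  den <- stats::integrate(kern, -Inf, Inf, rel.tol = 1e-11)$value
  num <- stats::integrate(function(th) f(th) * kern(th), -Inf, Inf,
                          rel.tol = 1e-11)$value
  num / den
}

#' Look up a built-in problem by id
#'
#' @param id `"t1"`, `"t2"` or `"gauss"`.
#' @param params Named list of constructor arguments overriding defaults.
#' @return An [abc_problem].
#' @export
get_problem <- function(id, params = list()) {
  ctor <- switch(id,
                 t1 = problem_t1,
                 t2 = problem_t2,
                 gauss = problem_gauss,
                 stop("unknown problem id: ", id))
  do.call(ctor, params)
}

#' Pre-defined acceptance-threshold schedules for the built-in problems
#'
#' Fixed strictly decreasing threshold lists used by the package's own
#' experiments, chosen once from the prior-predictive distance distribution
#' of each problem (roughly successive halvings starting near its median)
#' so that acceptance rates stay practical over all generations. Fixed
#' schedules also make runs directly comparable across scheduling
#' strategies.
#'
#' @param id `"t1"`, `"t2"` or `"gauss"`.
#' @param n_generations Number of generations (truncates or errors if
#'   longer than the stored list).
#' @return An [epsilon_fixed()] schedule.
#' @export
default_epsilon_schedule <- function(id, n_generations = NULL) {
  values <- switch(id,
                   t1 = c(2, 1.2, 0.8, 0.5, 0.3),
                   t2 = c(0.9, 0.63, 0.45, 0.32, 0.22, 0.16, 0.11, 0.08),
                   gauss = c(1.5, 1, 0.7, 0.5),
                   stop("unknown problem id: ", id))
  if (!is.null(n_generations)) {
    stopifnot(n_generations <= length(values))
    values <- values[seq_len(n_generations)]
  }
  epsilon_fixed(values)
}
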