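#' Define an ABC inference problem
#'
#' Bundles the ingredients of a likelihood-free inference problem: a prior,
#' a stochastic model simulator, a declared simulation-duration model, a
#' distance function, and the observed data. Data are assumed to already be
#' (or incorporate) summary statistics.
#'
#' The duration model declares how many simulated seconds one model
#' evaluation takes; the simulated scheduling backend advances its clock by
#' these declared durations and never sleeps or measures real wall-clock
#' time.
#'
#' @param prior An `abc_proposal` (e.g. [uniform_prior()], [normal_prior()])
#'   used both to sample initial particles and to evaluate the prior density.
#' @param model Function `theta -> y`: simulates one data set (numeric
#'   vector) from the model at parameter `theta`, drawing from the R RNG.
#' @param duration Function `theta -> seconds >= 0`: declared simulation
#'   duration for one model evaluation at `theta`, drawing from the R RNG.
#' @param distance Function `(y, y_obs) -> d >= 0`.
#' @param observed Observed data `y_obs` (numeric vector).
#' @param n_theta Parameter dimension.
#' @param name Identifier used in outputs.
#' @return An object of class `abc_problem`.
#' @seealso [problem_t1()], [problem_t2()], [problem_gauss()]
#' @export
abc_problem <- function(prior, model, duration, distance, observed, n_theta,
                        name = "custom") {
  stopifnot(inherits(prior, "abc_proposal"),
            is.function(model), is.function(duration), is.function(distance),
            is.numeric(observed),
            is.numeric(n_theta), n_theta >= 1)
  structure(list(prior = prior, model = model, duration = duration,
                 distance = distance, observed = observed,
                 n_theta = as.integer(n_theta), name = name),
            class = "abc_problem")
}

#' @export
print.abc_problem <- function(x, ...) {
  cat(sprintf("<abc_problem> '%s': n_theta = %d, |y_obs| = %d\n",
              x$name, x$n_theta, length(x$observed)))
  invisible(x)
}

#' Simulate one particle's data and declared duration
#'
#' Runs the model and the duration model at `theta`, each under its own RNG
#' substream, so scheduler interleaving cannot perturb the draws.
#'
#' @param problem An [abc_problem].
#' @param theta Numeric parameter vector.
#' @param rng An [rng_streams] object.
#' @return A list with elements `y` (simulated data), `duration` (simulated
#'   seconds), and `distance` to the observed data.
#' @export
simulate_problem <- function(problem, theta, rng) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == problem$n_theta, all(is.finite(theta)))
  y <- rng_eval(rng, "simulator", problem$model(theta))
  du <- rng_eval(rng, "durations", problem$duration(theta))
  if (!is.finite(du) || du < 0) stop("declared duration must be finite and >= 0")
  list(y = y, duration = du, distance = problem$distance(y, problem$observed))
}

#' Acceptance decision for a simulated particle
#'
#' A particle is accepted iff its distance to the observed data does not
#' exceed the current threshold (closed comparison, `<=`). The decision
#' depends only on `(distance, epsilon)`, never on scheduling timestamps.
#' A non-finite distance signals a pathological simulation and is rejected
#' with a warning.
#'
#' @param particle A list with at least a numeric `distance` element, or a
#'   single numeric distance.
#' @param epsilon Acceptance threshold, `> 0`.
#' @return Logical: accepted or not.
#' @examples
#' evaluate_acceptance(list(distance = 0.3), 0.5)  # TRUE
#' evaluate_acceptance(list(distance = 0.5), 0.5)  # TRUE (boundary)
#' @export
evaluate_acceptance <- function(particle, epsilon) {
  d <- if (is.list(particle)) particle$distance else particle
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  if (length(d) != 1L || !is.numeric(d))
    stop("particle must carry a single numeric distance")
  if (!is.finite(d)) {
    warning("non-finite distance; particle rejected")
    return(FALSE)
  }
  d <= epsilon
}

#' Weighted population of accepted particles
#'
#' Internal constructor assembling a generation's population: the particle
#' table, per-subpopulation normalized weights, ESS, mixing coefficients
#' beta, and the combined (estimation-ready) weights.
#'
#' @param particles data.frame with columns `generation`, `proposal_id`,
#'   `theta_*`, `distance`, `weight` (raw), `start_time`, `end_time`.
#' @param epsilon Threshold realized for this generation.
#' @param generation Generation index.
#' @param beta_rule `"ess"` (ESS-optimal) or `"count"` (proportional to
#'   subpopulation size).
#' @return An object of class `abc_population`.
#' @keywords internal
new_population <- function(particles, epsilon, generation,
                           beta_rule = "ess") {
  ids <- unique(particles$proposal_id)
  # preliminary subpopulation (id containing "~") first, for readability
  ids <- ids[order(!grepl("~", ids, fixed = TRUE), ids)]
  wl <- lapply(ids, function(id) particles$weight[particles$proposal_id == id])
  comb <- combine_subpopulations(wl, beta_rule = beta_rule)
  particles$norm_weight <- NA_real_
  particles$comb_weight <- NA_real_
  for (k in seq_along(ids)) {
    sel <- particles$proposal_id == ids[k]
    particles$norm_weight[sel] <- comb$normalized[[k]]
    particles$comb_weight[sel] <- comb$combined[[k]]
  }
  n_tilde <- sum(grepl("~", particles$proposal_id, fixed = TRUE))
  structure(list(particles = particles,
                 epsilon = epsilon,
                 generation = generation,
                 subpopulation_ids = ids,
                 betas = stats::setNames(comb$betas, ids),
                 ess = stats::setNames(comb$ess, ids),
                 n_tilde = n_tilde,
                 n = nrow(particles)),
            class = "abc_population")
}

#' @export
print.abc_population <- function(x, ...) {
  cat(sprintf(
    "<abc_population> generation %d: N = %d, epsilon = %.4g, N~ = %d, ESS = %.1f\n",
    x$generation, x$n, x$epsilon, x$n_tilde, population_ess(x)))
  invisible(x)
}

#' Total effective sample size of a population
#'
#' ESS of the combined weights of a population.
#'
#' @param pop An `abc_population`.
#' @return Scalar ESS.
#' @export
population_ess <- function(pop) {
  effective_sample_size(pop$particles$comb_weight)
}

#' Extract the parameter matrix of a population
#'
#' @param pop An `abc_population`.
#' @return Numeric matrix, one row per particle.
#' @export
population_theta <- function(pop) {
  cols <- grep("^theta_", names(pop$particles), value = TRUE)
  as.matrix(pop$particles[, cols, drop = FALSE])
}
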