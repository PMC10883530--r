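#' Effective sample size of an importance-weighted sample
#'
#' `ESS(w) = (sum w)^2 / sum(w^2)`, a standard measure of weight imbalance:
#' it equals `N` for uniform weights and 1 for a point mass, and is invariant
#' to positive rescaling of all weights.
#'
#' @param weights Nonnegative numeric vector. An empty vector, or one with
#'   all weights zero, returns 0 by convention (empty subpopulation).
#' @return Scalar in `{0} U [1, length(weights)]`.
#' @examples
#' effective_sample_size(c(1, 1, 1, 1))  # 4
#' effective_sample_size(c(5, 0, 0))     # 1
#' @export
effective_sample_size <- function(weights) {
  if (length(weights) == 0L) return(0)
  if (!is.numeric(weights) || any(!is.finite(weights)))
    stop("weights must be finite numerics")
  if (any(weights < 0)) stop("negative weight")
  s <- sum(weights)
  if (s == 0) return(0)
  s^2 / sum(weights^2)
}

#' Importance weight of a particle
#'
#' The non-normalized weight `w(theta) = pi(theta) / g(theta)`, the
#' Radon-Nikodym derivative of the prior with respect to the proposal the
#' particle was drawn from. In the first generation particles are drawn from
#' the prior itself, so all weights are 1.
#'
#' @param theta Numeric parameter vector (or matrix of row vectors).
#' @param prior,proposal `abc_proposal` objects.
#' @return Numeric weight(s), finite and `>= 0`. A proposal density of zero
#'   where the prior has mass is an error: it violates the support condition
#'   `g >> pi` required for unbiasedness.
#' @export
importance_weight <- function(theta, prior, proposal) {
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
  p <- proposal_density(prior, th)
  g <- proposal_density(proposal, th)
  bad <- g == 0 & p > 0
  if (any(bad))
    stop("proposal density is zero where the prior has mass (support condition violated)")
  w <- ifelse(p == 0, 0, p / g)
  if (any(!is.finite(w))) stop("non-finite importance weight")
  w
}

#' ESS-optimal mixing coefficients for subpopulation estimates
#'
#' When a generation is assembled from particles of several proposals, each
#' subpopulation is self-normalized separately and the subpopulation
#' estimates are mixed with coefficients `beta_k`. Choosing `beta` to
#' maximize the effective sample size of the combined weights gives
#' `beta_k = ESS_k / sum_j ESS_j`: each subpopulation contributes in
#' proportion to its effective sample size. An empty subpopulation (ESS 0)
#' receives `beta = 0`, so the estimator degrades gracefully to the ordinary
#' single-proposal case.
#'
#' @param ess_list Numeric vector of `K >= 1` subpopulation ESS values,
#'   each `>= 0`, not all zero.
#' @return Numeric vector of `K` coefficients summing to 1.
#' @examples
#' optimal_beta(c(10, 30))  # c(0.25, 0.75)
#' @export
optimal_beta <- function(ess_list) {
  stopifnot(is.numeric(ess_list), length(ess_list) >= 1L)
  if (any(ess_list < 0)) stop("ESS values must be >= 0")
  s <- sum(ess_list)
  if (s == 0) stop("all subpopulations empty: no usable particles")
  ess_list / s
}

#' Combine subpopulation weights into one normalized estimator
#'
#' Self-normalizes each subpopulation's raw weights separately (the weight
#' functions of different proposals have different, unknown normalization
#' constants, so raw weights are not directly comparable across
#' subpopulations), then mixes them with coefficients `beta`. The combined
#' effective weight of particle `i` of subpopulation `k` is
#' `beta_k * W_k^i`; combined weights sum to 1 over the whole population.
#' With a single nonempty subpopulation this reduces exactly to the ordinary
#' self-normalized estimator.
#'
#' @param weights_list List of `K` nonnegative raw-weight vectors (empty
#'   vectors allowed).
#' @param beta_rule `"ess"` for the ESS-optimal rule ([optimal_beta]) or
#'   `"count"` for `beta_k` proportional to the subpopulation size.
#' @return List with elements `betas`, `ess`, `normalized` (list of
#'   per-subpopulation normalized weights) and `combined` (list of combined
#'   effective weights, summing to 1 overall).
#' @export
combine_subpopulations <- function(weights_list, beta_rule = c("ess", "count")) {
  beta_rule <- match.arg(beta_rule)
  stopifnot(is.list(weights_list), length(weights_list) >= 1L)
  ess <- vapply(weights_list, effective_sample_size, numeric(1))
  betas <- if (beta_rule == "ess") {
    optimal_beta(ess)
  } else {
    n <- vapply(weights_list, function(w) sum(w > 0) > 0, logical(1)) *
      lengths(weights_list)
    if (sum(n) == 0) stop("all subpopulations empty: no usable particles")
    n / sum(n)
  }
  normalized <- lapply(weights_list, function(w) {
    s <- sum(w)
    if (length(w) == 0L || s == 0) rep(0, length(w)) else w / s
  })
  combined <- mapply(function(W, b) b * W, normalized, betas, SIMPLIFY = FALSE)
  list(betas = betas, ess = ess, normalized = normalized, combined = combined)
}

#' Posterior expectation under a combined weighted population
#'
#' Self-normalized importance estimator `sum_i omega_i f(theta_i)` over all
#' particles, with `omega` the combined weights.
#'
#' @param pop An `abc_population`, or a list with elements `theta` (matrix)
#'   and `comb_weight` (vector summing to 1).
#' @param f Function mapping one parameter vector to a scalar. Defaults to
#'   the first parameter component.
#' @return Scalar estimate.
#' @export
weighted_expectation <- function(pop, f = function(theta) theta[1L]) {
  if (inherits(pop, "abc_population")) {
    th <- population_theta(pop)
    w <- pop$particles$comb_weight
  } else {
    th <- pop$theta
    w <- pop$comb_weight
  }
  fv <- apply(th, 1L, f)
  sum(w * fv)
}

#' Grid-search maximizer of the combined ESS (independent check)
#'
#' Brute-force search for the mixing coefficient `beta` maximizing the ESS
#' of the concatenated weights `(beta * W1, (1 - beta) * W2)` for two
#' normalized subpopulations. Exists as an independent cross-check of the
#' closed form in [optimal_beta]; it is never used by the sampler.
#'
#' @param w1,w2 Raw weight vectors of the two subpopulations.
#' @param step Grid resolution in `[0, 1]`.
#' @return The grid value of `beta` with maximal combined ESS.
#' @export
grid_beta <- function(w1, w2, step = 1e-4) {
  W1 <- if (sum(w1) > 0) w1 / sum(w1) else rep(0, length(w1))
  W2 <- if (sum(w2) > 0) w2 / sum(w2) else rep(0, length(w2))
  grid <- seq(0, 1, by = step)
  s1 <- sum(W1^2); s2 <- sum(W2^2)
  # ESS(beta) = 1 / (beta^2 * sum W1^2 + (1-beta)^2 * sum W2^2)
  denom <- grid^2 * s1 + (1 - grid)^2 * s2
  grid[which.min(denom)]
}
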