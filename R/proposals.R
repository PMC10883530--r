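#' Proposal distributions
#'
#' An `abc_proposal` is a sampleable, density-evaluable distribution over
#' parameters: the prior itself, or a Gaussian kernel mixture built from a
#' weighted population. The generation-t proposal first selects an accepted
#' particle of generation t-1 (with probability proportional to its combined
#' weight) and then perturbs it with a shared multivariate normal kernel.
#'
#' @name abc_proposal
#' @keywords internal
NULL

new_proposal <- function(sample, density, source, generation = NA_integer_,
                         extra = list()) {
  structure(c(list(sample = sample, density = density, source = source,
                   generation = generation), extra),
            class = "abc_proposal")
}

#' @export
print.abc_proposal <- function(x, ...) {
  cat(sprintf("<abc_proposal> source = %s%s\n", x$source,
              if (!is.na(x$generation)) sprintf(" (built from generation %d)",
                                                x$generation) else ""))
  invisible(x)
}

#' Sample parameter vectors from a proposal
#' @param proposal An `abc_proposal`.
#' @param n Number of draws.
#' @return Numeric matrix, `n` rows.
#' @export
proposal_sample <- function(proposal, n = 1L) proposal$sample(n)

#' Evaluate a proposal density
#' @param proposal An `abc_proposal`.
#' @param theta Numeric vector or matrix of row vectors.
#' @return Numeric density value(s), `>= 0`.
#' @export
proposal_density <- function(proposal, theta) {
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
  proposal$density(th)
}

#' Independent-uniform prior
#'
#' @param lower,upper Numeric bound vectors (recycled to equal length).
#' @return An `abc_proposal` with `source = "prior"`.
#' @export
uniform_prior <- function(lower, upper) {
  k <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), k)
  upper <- rep_len(as.numeric(upper), k)
  stopifnot(all(upper > lower))
  vol <- prod(upper - lower)
  new_proposal(
    sample = function(n) {
      matrix(stats::runif(n * k, rep(lower, each = n), rep(upper, each = n)),
             nrow = n)
    },
    density = function(th) {
      inside <- rep(TRUE, nrow(th))
      for (j in seq_len(k))
        inside <- inside & th[, j] >= lower[j] & th[, j] <= upper[j]
      ifelse(inside, 1 / vol, 0)
    },
    source = "prior")
}

#' Independent-normal prior
#'
#' @param mean,sd Numeric vectors of component means and standard deviations
#'   (recycled to equal length).
#' @return An `abc_proposal` with `source = "prior"`.
#' @export
normal_prior <- function(mean = 0, sd = 1) {
  k <- max(length(mean), length(sd))
  mean <- rep_len(as.numeric(mean), k)
  sd <- rep_len(as.numeric(sd), k)
  stopifnot(all(sd > 0))
  new_proposal(
    sample = function(n) {
      matrix(stats::rnorm(n * k, rep(mean, each = n), rep(sd, each = n)),
             nrow = n)
    },
    density = function(th) {
      d <- rep(1, nrow(th))
      for (j in seq_len(k)) d <- d * stats::dnorm(th[, j], mean[j], sd[j])
      d
    },
    source = "prior")
}

#' Perturbation-kernel configuration
#'
#' The shared kernel covariance is the previous generation's weighted sample
#' covariance (plain weighted second moment about the weighted mean, using
#' the combined normalized weights), multiplied by `scale_factor`, plus a
#' small diagonal jitter `jitter * trace(Sigma) / n_theta` guarding against
#' numerically singular covariances for degenerate populations.
#'
#' @param scale_factor Multiplier on the weighted sample covariance
#'   (default 2, the classic adaptive choice).
#' @param jitter Relative diagonal jitter (default 1e-10).
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(scale_factor = 2, jitter = 1e-10) {
  stopifnot(scale_factor > 0, jitter >= 0)
  structure(list(scale_factor = scale_factor, jitter = jitter),
            class = "kernel_config")
}

#' Weighted sample covariance
#'
#' Plain weighted second moment about the weighted mean (no small-sample
#' correction), with self-normalized weights.
#'
#' @param theta Numeric matrix, one row per particle.
#' @param weights Nonnegative weights.
#' @return Covariance matrix.
#' @export
weighted_cov <- function(theta, weights) {
  th <- if (is.matrix(theta)) theta else matrix(theta, ncol = 1L)
  w <- weights / sum(weights)
  mu <- colSums(th * w)
  d <- sweep(th, 2L, mu)
  crossprod(d, d * w)
}

#' Gaussian kernel-mixture proposal
#'
#' Mixture of normals centered at the given particles, with mixture weights
#' proportional to the particle weights and a shared covariance.
#'
#' @param means Numeric matrix of component centers (one row per particle).
#' @param weights Nonnegative mixture weights (normalized internally).
#' @param sigma Shared covariance matrix (symmetric positive definite).
#' @param generation Generation the mixture was built from (bookkeeping).
#' @return An `abc_proposal` with `source = "kernel_mixture"`. Its density
#'   is strictly positive everywhere, so the support condition `g >> pi`
#'   holds for any prior.
#' @export
kernel_mixture <- function(means, weights, sigma, generation = NA_integer_) {
  means <- if (is.matrix(means)) means else matrix(means, ncol = 1L)
  k <- ncol(means)
  sigma <- as.matrix(sigma)
  stopifnot(nrow(means) == length(weights), all(weights >= 0),
            sum(weights) > 0, nrow(sigma) == k, ncol(sigma) == k)
  w <- weights / sum(weights)
  R <- tryCatch(chol(sigma),
                error = function(e) stop("singular kernel covariance"))
  Rinv <- backsolve(R, diag(k))
  logdet <- 2 * sum(log(diag(R)))
  lognorm <- -0.5 * (k * log(2 * pi) + logdet)
  cw <- cumsum(w)
  new_proposal(
    sample = function(n) {
      idx <- findInterval(stats::runif(n), cw) + 1L
      z <- matrix(stats::rnorm(n * k), nrow = n)
      means[idx, , drop = FALSE] + z %*% R
    },
    density = function(th) {
      out <- numeric(nrow(th))
      for (i in seq_len(nrow(th))) {
        d <- sweep(means, 2L, th[i, ])
        q <- rowSums((d %*% Rinv)^2)
        out[i] <- sum(w * exp(lognorm - 0.5 * q))
      }
      out
    },
    source = "kernel_mixture", generation = generation,
    extra = list(means = means, weights = w, sigma = sigma))
}

#' Build the generation-t proposal from an accepted population
#'
#' Kernel mixture over the population's particles with mixture weights
#' proportional to their combined normalized weights and shared covariance
#' `scale_factor * weighted_cov + jitter` (see [kernel_config()]).
#'
#' Perturbed draws may land outside the prior support; such particles get
#' prior density 0, hence raw weight 0, and are effectively discarded at the
#' weighting stage. This keeps the proposal density exact (no truncation).
#'
#' @param pop An `abc_population`.
#' @param cfg A [kernel_config()].
#' @return An `abc_proposal`.
#' @export
build_proposal <- function(pop, cfg = kernel_config()) {
  stopifnot(inherits(pop, "abc_population"))
  th <- population_theta(pop)
  w <- pop$particles$comb_weight
  if (sum(w) <= 0) stop("population has no positive weights")
  sigma <- cfg$scale_factor * weighted_cov(th, w)
  jit <- cfg$jitter * sum(diag(sigma)) / ncol(th)
  diag(sigma) <- diag(sigma) + jit
  kernel_mixture(th, w, sigma, generation = pop$generation)
}

#' Build the preliminary proposal for look-ahead sampling
#'
#' As soon as the required number of acceptances for generation t-1 is
#' reached, look-ahead scheduling builds a preliminary proposal for
#' generation t from partial information:
#' * `mode = "prel"`: a kernel mixture from the preliminary population of
#'   the first N acceptances (finish order) of generation t-1. Fast, but
#'   with parameter-dependent run-times the early finishers over-represent
#'   fast-simulating regions, which can bias the proposal.
#' * `mode = "past"`: simply reuse the generation t-1 proposal object (for
#'   t = 2 this is the prior), which is free of run-time bias by induction.
#'
#' @param mode `"prel"` or `"past"`.
#' @param preliminary_pop For `"prel"`: the preliminary `abc_population`.
#' @param previous_proposal For `"past"`: the proposal used in the previous
#'   generation (returned as-is, not rebuilt).
#' @param cfg A [kernel_config()].
#' @return An `abc_proposal`.
#' @export
build_preliminary_proposal <- function(mode = c("prel", "past"),
                                       preliminary_pop = NULL,
                                       previous_proposal = NULL,
                                       cfg = kernel_config()) {
  mode <- match.arg(mode)
  if (mode == "past") {
    if (is.null(previous_proposal)) stop("previous proposal unavailable")
    return(previous_proposal)
  }
  if (is.null(preliminary_pop)) stop("preliminary population unavailable")
  build_proposal(preliminary_pop, cfg)
}
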