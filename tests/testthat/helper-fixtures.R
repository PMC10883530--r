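# Fixtures built in code: a problem with scripted (deterministic) durations
# and distances, consumed in launch order, for hand-traceable scheduler
# scenarios; plus small convenience wrappers.

scripted_problem <- function(durations, distances = 0) {
  di <- 0L
  si <- 0L
  abc_problem(
    prior = uniform_prior(-1, 1),
    model = function(theta) 0,
    duration = function(theta) {
      di <<- di + 1L
      durations[(di - 1L) %% length(durations) + 1L]
    },
    distance = function(y, y_obs) {
      si <<- si + 1L
      distances[(si - 1L) %% length(distances) + 1L]
    },
    observed = 0,
    n_theta = 1L,
    name = "scripted")
}

quick_run <- function(problem, strategy, W, N, epsilon, seed = 1L, ...) {
  abc_smc(problem,
          scheduler_config(strategy, n_workers = W, population_size = N, ...),
          epsilon, seed = seed)
}

final_pop <- function(run) run$populations[[run$n_generations]]

# combined-weight posterior mass of the positive mode (T1 diagnostics)
positive_mode_mass <- function(run) {
  pop <- final_pop(run)
  sum(pop$particles$comb_weight[population_theta(pop)[, 1L] > 0])
}

# random nonnegative weight vector with occasional zeros and heavy tails
random_weights <- function(n) {
  w <- stats::rlnorm(n, 0, runif(1, 0.1, 2))
  w[stats::runif(n) < 0.1] <- 0
  if (all(w == 0)) w[1L] <- 1
  w
}
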