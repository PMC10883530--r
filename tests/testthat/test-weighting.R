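test_that("effective sample size matches its definition", {
  expect_equal(effective_sample_size(c(1, 1, 1, 1)), 4)
  expect_equal(effective_sample_size(c(5, 0, 0)), 1)
  expect_equal(effective_sample_size(c(1, 2, 3)), 36 / 14)
  expect_equal(effective_sample_size(numeric(0)), 0)   # empty subpopulation
  expect_equal(effective_sample_size(c(0, 0)), 0)
  expect_error(effective_sample_size(c(1, -1)), "negative")
})

test_that("ESS bounds, scale invariance, and extremes hold over random vectors", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:50, 1L)
    w <- random_weights(n)
    e <- effective_sample_size(w)
    expect_gte(e, 1)
    expect_lte(e, n + 1e-12)
    expect_equal(effective_sample_size(w * runif(1, 1e-6, 1e6)), e,
                 tolerance = 1e-9)
  }
  # equality at N iff all (positive) weights equal
  expect_equal(effective_sample_size(rep(2.5, 17)), 17)
  expect_lt(effective_sample_size(c(rep(1, 16), 1.001)), 17)
})

test_that("importance weights are prior/proposal density ratios", {
  wide <- uniform_prior(-2, 2)    # density 0.25
  narrow <- uniform_prior(-1, 1)  # density 0.5
  expect_equal(importance_weight(0, narrow, wide), 2.0)
  # first generation: proposal is the prior itself
  th <- matrix(seq(-0.9, 0.9, length.out = 7))
  expect_equal(importance_weight(th, narrow, narrow), rep(1, 7))
  # zero prior mass -> weight 0
  expect_equal(importance_weight(1.5, narrow, wide), 0)
  # proposal without support where the prior has mass -> hard error
  expect_error(importance_weight(1.5, wide, narrow), "support")
})

test_that("closed-form beta is ESS-proportional and matches the grid oracle", {
  expect_equal(optimal_beta(c(10, 30)), c(0.25, 0.75))
  expect_equal(optimal_beta(7), 1)
  expect_equal(optimal_beta(c(0, 12)), c(0, 1))
  expect_error(optimal_beta(c(0, 0)), "empty")
  set.seed(7)
  for (i in 1:25) {
    w1 <- random_weights(sample(2:40, 1L))
    w2 <- random_weights(sample(2:40, 1L))
    b <- optimal_beta(c(effective_sample_size(w1), effective_sample_size(w2)))
    expect_equal(b[1L], grid_beta(w1, w2), tolerance = 1e-3)
  }
})

test_that("subpopulation combination normalizes, mixes, and reduces correctly", {
  # single subpopulation: exact reduction to the self-normalized estimator
  one <- combine_subpopulations(list(c(0.2, 0.8)))
  expect_equal(one$combined[[1L]], c(0.2, 0.8))
  expect_equal(one$betas, 1)

  # two uniform subpopulations of two particles each: all weights 1/4
  two <- combine_subpopulations(list(c(1, 1), c(3, 3)))
  expect_equal(unlist(two$combined), rep(0.25, 4))

  # point mass (ESS 1) vs uniform pair (ESS 2): beta = (1/3, 2/3)
  mix <- combine_subpopulations(list(1.0, c(0.5, 0.5)))
  expect_equal(mix$betas, c(1, 2) / 3)
  expect_equal(unlist(mix$combined), rep(1 / 3, 3))

  # combined weights always sum to one
  set.seed(11)
  for (i in 1:50) {
    wl <- list(random_weights(5), random_weights(8), random_weights(3))
    cmb <- combine_subpopulations(wl)
    expect_equal(sum(unlist(cmb$combined)), 1, tolerance = 1e-12)
    expect_equal(sum(cmb$betas), 1, tolerance = 1e-12)
  }
})

test_that("per-subpopulation normalization makes raw scales irrelevant", {
  # the weight functions of different proposals have different normalization
  # constants; rescaling one subpopulation's raw weights must change nothing
  set.seed(12)
  w1 <- random_weights(20); w2 <- random_weights(30)
  base <- combine_subpopulations(list(w1, w2))
  for (c_scale in c(1e-6, 0.37, 1, 540)) {
    alt <- combine_subpopulations(list(w1 * c_scale, w2))
    expect_equal(alt$betas, base$betas, tolerance = 1e-12)
    expect_equal(alt$combined, base$combined, tolerance = 1e-12)
  }
})

test_that("weighted expectation is the combined-weight dot product", {
  pop <- list(theta = matrix(c(0, 3, 6)), comb_weight = rep(1 / 3, 3))
  expect_equal(weighted_expectation(pop), 3.0)
  expect_equal(weighted_expectation(pop, function(th) 1), 1.0)
  sym <- list(theta = matrix(c(-1, 1)), comb_weight = c(0.5, 0.5))
  expect_equal(weighted_expectation(sym), 0.0)
})

test_that("count-rule mixing converges to the alpha-mixture of subpopulation estimates", {
  # with beta = N1/N the combined estimator is exactly the alpha-mixture;
  # the ESS-optimal beta agrees with it asymptotically when both
  # subpopulations target the same distribution
  set.seed(21)
  n <- 4000L; alpha <- 0.3
  w1 <- random_weights(round(alpha * n)); w2 <- random_weights(n - round(alpha * n))
  f1 <- rnorm(length(w1), 1, 1); f2 <- rnorm(length(w2), 1, 1)
  est <- function(w, f) sum(w * f) / sum(w)
  cnt <- combine_subpopulations(list(w1, w2), beta_rule = "count")
  mixed <- sum(unlist(cnt$combined) * c(f1, f2))
  expect_equal(mixed, alpha * est(w1, f1) + (1 - alpha) * est(w2, f2),
               tolerance = 1e-10)
  opt <- combine_subpopulations(list(w1, w2), beta_rule = "ess")
  expect_equal(sum(unlist(opt$combined) * c(f1, f2)), mixed, tolerance = 0.05)
})
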