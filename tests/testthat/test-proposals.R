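test_that("a one-component kernel mixture is the component normal", {
  p <- kernel_mixture(matrix(0), 1, matrix(1))
  th <- matrix(seq(-3, 3, by = 0.5))
  expect_equal(proposal_density(p, th), dnorm(th[, 1L]), tolerance = 1e-12)
})

test_that("equally weighted components at +/-1 give a symmetric density", {
  p <- kernel_mixture(matrix(c(-1, 1)), c(1, 1), matrix(0.49))
  th <- seq(0.1, 2.4, by = 0.1)
  expect_equal(proposal_density(p, matrix(th)), proposal_density(p, matrix(-th)),
               tolerance = 1e-12)
})

test_that("weighted covariance and the kernel scale factor behave as documented", {
  th <- matrix(c(-1, 1))
  expect_equal(weighted_cov(th, c(1, 1))[1L, 1L], 1)  # second moment, no correction
  df <- data.frame(generation = 1L, proposal_id = "g1", theta_1 = c(-1, 1),
                   distance = 0, weight = c(1, 1), start_time = 0, end_time = 1,
                   launch_index = 1:2)
  pop <- abclook:::new_population(df, epsilon = 1, generation = 1L)
  prop <- build_proposal(pop, kernel_config(scale_factor = 2))
  expect_equal(prop$sigma[1L, 1L], 2, tolerance = 1e-8)
  # weighted mean/cov respond to the weights
  expect_equal(weighted_cov(th, c(3, 1))[1L, 1L], 4 * 3 * 1 / 16)
})

test_that("kernel mixtures are supported everywhere (g >> pi for any prior)", {
  set.seed(3)
  p <- kernel_mixture(matrix(rnorm(5)), runif(5), matrix(0.2))
  # points many kernel sds from every component (within floating-point range)
  far <- matrix(c(-15, -5, 0, 5, 15))
  expect_true(all(proposal_density(p, far) > 0))
})

test_that("sampling agrees with the mixture density (mean within 4 SE)", {
  set.seed(17)
  means <- matrix(c(-2, 0, 3))
  w <- c(0.2, 0.5, 0.3)
  sig <- 0.8
  p <- kernel_mixture(means, w, matrix(sig))
  n <- 1e4L
  x <- proposal_sample(p, n)
  mu <- sum(w * means)
  v <- sum(w * (means^2 + sig)) - mu^2
  expect_lt(abs(mean(x) - mu), 4 * sqrt(v / n))
})

test_that("degenerate populations yield a singular-covariance error", {
  expect_error(kernel_mixture(matrix(c(0, 0)), c(1, 1), matrix(0)), "singular")
})

test_that("preliminary proposals follow the prel/past construction rules", {
  df <- data.frame(generation = 1L, proposal_id = "g1", theta_1 = c(-1, 0, 1),
                   distance = 0, weight = 1, start_time = 0, end_time = 1,
                   launch_index = 1:3)
  pop <- abclook:::new_population(df, epsilon = 1, generation = 1L)
  g_prev <- build_proposal(pop)
  # past: the previous proposal object is reused, not rebuilt
  expect_identical(build_preliminary_proposal("past", previous_proposal = g_prev),
                   g_prev)
  # past at t = 2 reduces to the prior when the previous proposal is g1 = prior
  pr <- uniform_prior(-2, 2)
  expect_identical(build_preliminary_proposal("past", previous_proposal = pr), pr)
  # prel: a kernel mixture built from the preliminary population
  g_tilde <- build_preliminary_proposal("prel", preliminary_pop = pop)
  expect_equal(proposal_density(g_tilde, matrix(0.3)),
               proposal_density(g_prev, matrix(0.3)))
  expect_error(build_preliminary_proposal("past"), "unavailable")
  expect_error(build_preliminary_proposal("prel"), "unavailable")
})

test_that("priors expose consistent samplers and densities", {
  u <- uniform_prior(c(0, -1), c(2, 1))
  expect_equal(proposal_density(u, c(1, 0)), 1 / 4)
  expect_equal(proposal_density(u, c(3, 0)), 0)
  set.seed(5)
  x <- proposal_sample(u, 500L)
  expect_true(all(x[, 1L] >= 0 & x[, 1L] <= 2))
  nz <- normal_prior(1, 2)
  expect_equal(proposal_density(nz, 0), dnorm(0, 1, 2))
})
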