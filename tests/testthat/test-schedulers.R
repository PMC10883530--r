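test_that("static scheduling defines exactly N tasks and queues them", {
  # W = 8, N = 5, unit durations, every draw accepted: one wave, 3 idle workers
  run <- quick_run(scripted_problem(1), "stat", W = 8, N = 5,
                   epsilon_fixed(1), max_generations = 1)
  expect_equal(run$wall_time, 1)
  expect_equal(run$n_simulations, 5L)
  expect_equal(run$idle_fraction, 3 / 8)

  # W = 2, N = 2, durations 3 and 5: generation ends with the slower task
  run2 <- quick_run(scripted_problem(c(3, 5)), "stat", W = 2, N = 2,
                    epsilon_fixed(1), max_generations = 1)
  expect_equal(run2$wall_time, 5)

  # N > W: tasks queue, 5 unit tasks on 2 workers take 3 waves
  run3 <- quick_run(scripted_problem(1), "stat", W = 2, N = 5,
                    epsilon_fixed(1), max_generations = 1)
  expect_equal(run3$wall_time, 3)
  expect_equal(run3$n_simulations, 5L)

  # a task keeps sampling on its worker until acceptance
  run4 <- quick_run(scripted_problem(1, distances = c(1, 0)), "stat",
                    W = 1, N = 2, epsilon_fixed(0.5), max_generations = 1)
  expect_equal(run4$n_simulations, 4L)
  expect_equal(run4$wall_time, 4)
})

test_that("dynamic scheduling keeps the earliest-started accepted particles", {
  # W = 2, N = 2, durations [3,5,1] in launch order, all accepted:
  # acceptances at t=3,4; wait for the straggler until t=5; the surplus
  # particle (started at t=3) is accepted but discarded
  run <- quick_run(scripted_problem(c(3, 5, 1)), "dyn", W = 2, N = 2,
                   epsilon_fixed(1), max_generations = 1)
  expect_equal(run$wall_time, 5)
  expect_equal(run$n_simulations, 3L)
  expect_equal(sum(run$tasks$accepted), 3L)  # N~_all = 3
  pop <- final_pop(run)
  expect_equal(sort(pop$particles$start_time), c(0, 0))
  expect_equal(run$idle_fraction, 1 / 10)  # worker 1 idle on [4,5]

  # simultaneous starts: deterministic tie-break by launch sequence number
  run2 <- quick_run(scripted_problem(1), "dyn", W = 3, N = 2,
                    epsilon_fixed(1), max_generations = 1)
  expect_equal(final_pop(run2)$particles$launch_index, c(1L, 2L))
})

test_that("first-started selection is stable, deterministic, and validated", {
  acc <- data.frame(start_time = c(0, 0, 3), launch_index = 1:3)
  sel <- select_first_started(acc, 2)
  expect_equal(sel$launch_index, c(1L, 2L))
  expect_equal(select_first_started(acc, 3), acc)  # identity at n = len
  ties <- data.frame(start_time = rep(1, 4), launch_index = c(4L, 2L, 3L, 1L))
  expect_equal(select_first_started(ties, 2)$launch_index, c(1L, 2L))
  expect_error(select_first_started(acc, 4), "fewer")
})

test_that("look-ahead fills the straggler window with next-generation work", {
  # W = 2, N = 1, two generations; gen-1 durations [2,9], prelims take 3 s.
  # After the first acceptance at t=2, worker 1 samples generation 2 from
  # the preliminary proposal (here the prior, LA Past at t=2) during [2,9].
  p <- scripted_problem(c(2, 9, 3, 3, 3))
  run <- quick_run(p, "la_past", W = 2, N = 1,
                   epsilon_fixed(c(1, 0.5)), max_generations = 2)
  expect_equal(run$n_generations, 2L)
  expect_equal(run$close_times, c(9, 11))
  expect_equal(run$wall_time, 11)
  gen2 <- run$tasks[run$tasks$generation == 2L, ]
  expect_equal(nrow(gen2), 3L)                       # three prelim launches
  expect_true(all(grepl("~", gen2$proposal_id)))
  expect_equal(gen2$start_time, c(2, 5, 8))
  pop2 <- final_pop(run)
  expect_equal(pop2$n_tilde, 1L)
  expect_equal(pop2$particles$start_time, 2)          # earliest-started prelim
  expect_equal(pop2$particles$weight, 1)              # g~_2 = g_1 = prior
  # worker 2 idles on [9,11] once the run is predicted to terminate
  expect_equal(worker_occupancy(run)$idle_time, 2)
})

test_that("the preliminary-sample cap limits look-ahead launches", {
  p <- scripted_problem(c(1, 100, 100, 100, 1, 1))
  run <- quick_run(p, "la_past", W = 4, N = 1, epsilon_fixed(c(1, 0.5)),
                   max_generations = 2, prelim_cap_factor = 2)
  gen2 <- run$tasks[run$tasks$generation == 2L, ]
  expect_equal(nrow(gen2), 2L)  # cap = 2 * N, then the freed worker idles
  expect_equal(run$wall_time, 100)
  expect_equal(final_pop(run)$particles$start_time, 1)
})

test_that("look-ahead reduces exactly to dynamic scheduling without prelim launches", {
  # constant durations and W = N give synchronized waves: workers never
  # free up early, so no preliminary task is ever launched
  p <- problem_gauss(dur_sdlog = 0)
  eps <- default_epsilon_schedule("gauss", 3)
  dyn <- quick_run(p, "dyn", W = 30, N = 30, eps, seed = 9)
  la <- quick_run(p, "la_past", W = 30, N = 30, eps, seed = 9)
  expect_equal(sum(la$n_tilde), 0)
  expect_identical(dyn$populations, la$populations)
  expect_identical(dyn$wall_time, la$wall_time)
})

test_that("pre-defined and delayed acceptance evaluation agree for fixed thresholds", {
  p1 <- problem_t1()
  eps <- default_epsilon_schedule("t1", 3)
  for (s in c("la_past", "la_prel")) {
    direct <- abc_smc(p1, scheduler_config(s, 40, 20, max_generations = 3,
                                           delayed_evaluation = FALSE),
                      eps, seed = 5)
    delayed <- abc_smc(p1, scheduler_config(s, 40, 20, max_generations = 3,
                                            delayed_evaluation = TRUE),
                       eps, seed = 5)
    expect_identical(direct$populations, delayed$populations)
  }
})

test_that("identical seed and config reproduce a run bit-for-bit", {
  p <- problem_t1()
  eps <- default_epsilon_schedule("t1", 3)
  r1 <- quick_run(p, "la_prel", W = 30, N = 20, eps, seed = 11)
  r2 <- quick_run(p, "la_prel", W = 30, N = 20, eps, seed = 11)
  expect_identical(r1$populations, r2$populations)
  expect_identical(r1$tasks, r2$tasks)
})

test_that("an unreachable threshold aborts at the simulation budget", {
  p <- scripted_problem(1, distances = 1)
  expect_error(
    quick_run(p, "dyn", W = 2, N = 2, epsilon_fixed(0.5),
              max_generations = 1, max_simulations = 50),
    "max_simulations")
})

test_that("occupancy accounting integrates the task timeline exactly", {
  run <- quick_run(problem_gauss(), "la_past", W = 10, N = 30,
                   default_epsilon_schedule("gauss", 3), seed = 2)
  occ <- worker_occupancy(run)
  dur <- pmin(run$tasks$end_time, run$wall_time) -
    pmin(run$tasks$start_time, run$wall_time)
  expect_equal(occ$busy_time, sum(dur))
  expect_equal(sum(occ$per_worker$busy_time), occ$busy_time)
  expect_equal(occ$idle_time + occ$busy_time, 10 * run$wall_time)
  expect_true(all(run$n_tilde_frac >= 0 & run$n_tilde_frac <= 1))
})

test_that("quantile-adaptive runs force delayed evaluation and terminate cleanly", {
  run <- quick_run(problem_gauss(), "la_past", W = 20, N = 40,
                   epsilon_quantile(0.5), seed = 4, max_generations = 4)
  expect_equal(run$n_generations, 4L)
  expect_true(all(diff(run$epsilon) < 0))
  expect_true(all(run$n_tilde_frac >= 0 & run$n_tilde_frac <= 1))
})
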