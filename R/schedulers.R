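#' Scheduler configuration
#'
#' Configures how the sampling work of each generation is distributed over a
#' pool of `n_workers` simulated workers:
#'
#' * `"stat"` (static): exactly `population_size` acceptance-tasks are
#'   defined per generation; each task samples until one particle is
#'   accepted. Tasks are queued if `N > W`; for `W > N` only `N` workers are
#'   ever busy.
#' * `"dyn"` (dynamic): sampling continues on all workers until `N`
#'   particles are accepted; all in-flight simulations then run to
#'   completion, and of all accepted particles only the `N` that *started*
#'   earliest form the population. Selecting by start (not finish) time
#'   removes the run-time bias towards fast-simulating parameters.
#' * `"la_prel"` / `"la_past"` (look-ahead): as `"dyn"`, but once `N`
#'   acceptances are reached, freed workers immediately start sampling the
#'   *next* generation from a preliminary proposal (built from the first `N`
#'   acceptances for `"la_prel"`, or reusing the current proposal for
#'   `"la_past"`), so workers never idle while stragglers finish.
#'
#' @param strategy One of `"stat"`, `"dyn"`, `"la_prel"`, `"la_past"`.
#' @param n_workers Number of simulated workers `W >= 1`.
#' @param population_size Particles per generation `N >= 1`.
#' @param max_generations Number of generations (may be bounded further by a
#'   fixed threshold schedule).
#' @param prelim_cap_factor At most `prelim_cap_factor * N` preliminary
#'   tasks are launched per generation (default 10); freed workers idle once
#'   the cap is reached.
#' @param delayed_evaluation `NULL` (auto: delayed iff the threshold
#'   schedule is adaptive) or logical. When delayed, preliminary particles'
#'   distances are computed on the workers but the acceptance decision is
#'   deferred until the previous population is finalized, so one common
#'   criterion applies to all particles of a generation.
#' @param selection `"first_started"` (correct, default) or
#'   `"first_finished"` (a deliberately run-time-biased selector, kept as a
#'   diagnostic to demonstrate the bias the start-time rule removes).
#' @param termination_prediction Suppress preliminary sampling when the run
#'   is predicted to terminate after the current generation (default TRUE).
#' @param post_process_time Simulated seconds of serial work between
#'   generations (default 0).
#' @param max_simulations Abort threshold on launched simulations per
#'   generation (guards against an unreachable threshold).
#' @return An object of class `scheduler_config`.
#' @export
scheduler_config <- function(strategy = c("dyn", "stat", "la_prel", "la_past"),
                             n_workers, population_size,
                             max_generations = Inf,
                             prelim_cap_factor = 10,
                             delayed_evaluation = NULL,
                             selection = c("first_started", "first_finished"),
                             termination_prediction = TRUE,
                             post_process_time = 0,
                             max_simulations = 1e6) {
  strategy <- match.arg(strategy)
  selection <- match.arg(selection)
  stopifnot(n_workers >= 1, population_size >= 1, prelim_cap_factor > 0,
            max_generations >= 1, post_process_time >= 0, max_simulations >= 1)
  structure(list(strategy = strategy,
                 n_workers = as.integer(n_workers),
                 population_size = as.integer(population_size),
                 max_generations = max_generations,
                 prelim_cap_factor = prelim_cap_factor,
                 delayed_evaluation = delayed_evaluation,
                 selection = selection,
                 termination_prediction = termination_prediction,
                 post_process_time = post_process_time,
                 max_simulations = max_simulations),
            class = "scheduler_config")
}

#' Select the n accepted particles that started earliest
#'
#' The run-time-bias correction shared by dynamic and look-ahead
#' scheduling: of all accepted particles, keep the `n` with the smallest
#' start time, breaking ties deterministically by launch sequence number.
#'
#' @param accepted data.frame with columns `start_time` and `launch_index`
#'   (launch sequence number).
#' @param n Number of particles to keep (`<= nrow(accepted)`).
#' @return The selected rows, in selection order.
#' @export
select_first_started <- function(accepted, n) {
  if (nrow(accepted) < n) stop("fewer than n accepted particles")
  ord <- order(accepted$start_time, accepted$launch_index)
  accepted[ord[seq_len(n)], , drop = FALSE]
}

#' Run an ABC-SMC sampler on the simulated worker pool
#'
#' Executes the full sequential sampler for `problem` under the scheduling
#' strategy in `scheduler`, on a deterministic discrete-event simulation of
#' `n_workers` parallel workers. Model evaluations advance the simulated
#' clock by the problem's declared durations; real wall-clock time is never
#' used. Identical `(seed, config)` yields a bit-identical result.
#'
#' @param problem An [abc_problem].
#' @param scheduler A [scheduler_config()].
#' @param epsilon An [epsilon_fixed()] or [epsilon_quantile()] schedule.
#' @param kernel A [kernel_config()].
#' @param seed Integer master seed for the named RNG substreams.
#' @param beta_rule Mixing rule for multi-proposal generations: `"ess"`
#'   (ESS-optimal, default) or `"count"` (proportional to subpopulation
#'   size).
#' @return An object of class `abc_run` with elements `populations` (list of
#'   `abc_population`), `epsilon`, `n_tilde`, `n_tilde_frac`, `betas`,
#'   `ess`, `wall_time`, `idle_fraction`, `close_times`, `tasks` (the full
#'   worker timeline, one row per simulation), `n_simulations`, `strategy`,
#'   and `config`.
#' @export
abc_smc <- function(problem, scheduler, epsilon, kernel = kernel_config(),
                    seed = 1L, beta_rule = c("ess", "count")) {
  beta_rule <- match.arg(beta_rule)
  stopifnot(inherits(problem, "abc_problem"),
            inherits(scheduler, "scheduler_config"),
            inherits(epsilon, "epsilon_schedule"))
  rng <- rng_streams(seed)
  run_engine(problem, scheduler, epsilon, kernel, rng, seed, beta_rule)
}

#' @rdname abc_smc
#' @param ... Passed on to [abc_smc()].
#' @export
run_static <- function(problem, scheduler, ...) {
  stopifnot(scheduler$strategy == "stat")
  abc_smc(problem, scheduler, ...)
}

#' @rdname abc_smc
#' @export
run_dynamic <- function(problem, scheduler, ...) {
  stopifnot(scheduler$strategy == "dyn")
  abc_smc(problem, scheduler, ...)
}

#' @rdname abc_smc
#' @export
run_lookahead <- function(problem, scheduler, ...) {
  stopifnot(scheduler$strategy %in% c("la_prel", "la_past"))
  abc_smc(problem, scheduler, ...)
}

# The discrete-event engine shared by all strategies. One "task" is one
# model simulation; its finish time is start + declared duration. The loop
# advances the clock to the earliest in-flight finish, processes all
# finishes at that instant (in worker order, deterministically), closes and
# finalizes generations whose acceptance target is met with nothing in
# flight, and then assigns work to free workers according to the strategy.
run_engine <- function(problem, sch, epsilon, kernel, rng, seed, beta_rule) {
  W <- sch$n_workers
  N <- sch$population_size
  strategy <- sch$strategy
  la <- strategy %in% c("la_prel", "la_past")
  stat <- strategy == "stat"
  nth <- problem$n_theta
  delayed <- sch$delayed_evaluation
  if (is.null(delayed)) delayed <- epsilon$kind == "quantile"

  n_t <- sch$max_generations
  if (epsilon$kind == "fixed") n_t <- min(n_t, length(epsilon$values))
  if (!is.finite(n_t))
    stop("an adaptive schedule needs a finite max_generations")
  n_t <- as.integer(n_t)
  cap_prelim <- as.integer(ceiling(sch$prelim_cap_factor * N))

  # --- task storage (grown by doubling) ---
  cap <- 2048L
  T_theta <- matrix(NA_real_, cap, nth)
  T_dist <- numeric(cap); T_start <- numeric(cap); T_end <- numeric(cap)
  T_gen <- integer(cap); T_worker <- integer(cap)
  T_prelim <- logical(cap); T_acc <- rep(NA, cap); T_eval <- logical(cap)
  ntask <- 0L

  grow <- function() {
    add <- cap
    cap <<- cap * 2L
    T_theta <<- rbind(T_theta, matrix(NA_real_, add, nth))
    length(T_dist) <<- cap; length(T_start) <<- cap; length(T_end) <<- cap
    length(T_gen) <<- cap; length(T_worker) <<- cap
    length(T_prelim) <<- cap; length(T_acc) <<- cap
    T_eval[(add + 1L):cap] <<- FALSE
  }

  # --- per-generation ledgers ---
  G_acc <- integer(n_t + 1L)        # accepted (evaluated) count
  G_inflight <- integer(n_t + 1L)
  G_assigned <- integer(n_t + 1L)   # STAT: acceptance-tasks assigned
  G_launched <- integer(n_t + 1L)   # simulations launched
  G_prelim <- integer(n_t + 1L)     # preliminary simulations launched
  acc_order <- vector("list", n_t + 1L)   # task ids in acceptance order
  pending <- vector("list", n_t + 1L)     # finished, not yet evaluated
  for (i in seq_len(n_t + 1L)) { acc_order[[i]] <- integer(); pending[[i]] <- integer() }
  eps <- rep(NA_real_, n_t + 1L)
  close_time <- rep(NA_real_, n_t)
  finalProp <- vector("list", n_t)
  prelimProp <- vector("list", n_t + 1L)
  populations <- vector("list", n_t)

  # --- workers ---
  w_finish <- rep(Inf, W); w_task <- integer(W); w_busy <- rep(FALSE, W)
  clock <- 0
  t_cur <- 1L
  done <- FALSE

  # g_t is built on demand (first launch or weight evaluation that needs
  # it): a generation fully covered by preliminary samples never constructs
  # its final kernel mixture
  get_final_prop <- function(t) {
    if (is.null(finalProp[[t]]))
      finalProp[[t]] <<- build_proposal(populations[[t - 1L]], kernel)
    finalProp[[t]]
  }

  launch <- function(wid, t, prelim_flag) {
    if (G_launched[t] >= sch$max_simulations)
      stop("max_simulations reached in generation ", t,
           " (acceptance threshold may be unreachable)")
    if (ntask + 1L > cap) grow()
    ntask <<- ntask + 1L
    i <- ntask
    prop <- if (prelim_flag) prelimProp[[t]] else get_final_prop(t)
    stream <- if (prop$source == "prior") "prior" else "perturbation"
    th <- as.numeric(rng_eval(rng, stream, prop$sample(1L)))
    # Perturbed draws outside the prior support have prior mass zero and can
    # never contribute; record an infinite distance instead of running the
    # model at an invalid parameter. The proposal density stays exact.
    in_support <- proposal_density(problem$prior, th) > 0
    if (in_support) {
      y <- rng_eval(rng, "simulator", problem$model(th))
      T_dist[i] <<- problem$distance(y, problem$observed)
    } else {
      T_dist[i] <<- Inf
    }
    du <- rng_eval(rng, "durations", problem$duration(th))
    T_theta[i, ] <<- th
    T_gen[i] <<- t; T_prelim[i] <<- prelim_flag; T_worker[i] <<- wid
    T_start[i] <<- clock; T_end[i] <<- clock + du
    w_busy[wid] <<- TRUE; w_finish[wid] <<- clock + du; w_task[wid] <<- i
    G_inflight[t] <<- G_inflight[t] + 1L
    G_launched[t] <<- G_launched[t] + 1L
    if (prelim_flag) G_prelim[t] <<- G_prelim[t] + 1L
    invisible(i)
  }

  eval_task <- function(i) {
    t <- T_gen[i]
    d <- T_dist[i]
    ok <- is.finite(d) && d <= eps[t]
    # Inf marks an out-of-support proposal (expected); NaN/NA signals a
    # pathological simulation and is worth a warning.
    if (is.na(d) || is.nan(d)) warning("non-finite distance; particle rejected")
    T_eval[i] <<- TRUE; T_acc[i] <<- ok
    if (ok) {
      G_acc[t] <<- G_acc[t] + 1L
      acc_order[[t]] <<- c(acc_order[[t]], i)
    }
    ok
  }

  on_finish <- function(wid) {
    i <- w_task[wid]
    t <- T_gen[i]
    w_busy[wid] <<- FALSE; w_finish[wid] <<- Inf
    G_inflight[t] <<- G_inflight[t] - 1L
    evaluate_now <- (t == t_cur) || (!delayed && !is.na(eps[t]))
    if (evaluate_now) {
      ok <- eval_task(i)
      # STAT: a task keeps sampling on its worker until it accepts
      if (stat && !ok) launch(wid, t, FALSE)
    } else {
      pending[[t]] <<- c(pending[[t]], i)
    }
    invisible(NULL)
  }

  weights_for <- function(t, sel) {
    if (t == 1L) return(rep(1, length(sel)))
    th <- T_theta[sel, , drop = FALSE]
    p <- proposal_density(problem$prior, th)
    w <- numeric(length(sel))
    pre <- T_prelim[sel]
    for (flag in unique(pre)) {
      m <- pre == flag
      prop <- if (flag) prelimProp[[t]] else get_final_prop(t)
      g <- proposal_density(prop, th[m, , drop = FALSE])
      if (any(g == 0 & p[m] > 0))
        stop("proposal density is zero where the prior has mass")
      w[m] <- ifelse(p[m] == 0, 0, p[m] / g)
    }
    w
  }

  finalize_pop <- function(t) {
    idx <- acc_order[[t]]
    key <- if (sch$selection == "first_finished") T_end[idx] else T_start[idx]
    sel <- idx[order(key, idx)][seq_len(N)]
    th <- T_theta[sel, , drop = FALSE]
    colnames(th) <- paste0("theta_", seq_len(nth))
    df <- data.frame(
      generation = t,
      proposal_id = ifelse(T_prelim[sel], sprintf("g~%d", t), sprintf("g%d", t)),
      th,
      distance = T_dist[sel],
      weight = weights_for(t, sel),
      start_time = T_start[sel],
      end_time = T_end[sel],
      launch_index = sel,
      stringsAsFactors = FALSE)
    new_population(df, epsilon = eps[t], generation = t, beta_rule = beta_rule)
  }

  ensure_prelim <- function(t_next) {
    if (!is.null(prelimProp[[t_next]])) return(invisible(NULL))
    t <- t_next - 1L
    if (strategy == "la_past") {
      prelimProp[[t_next]] <<- get_final_prop(t)
    } else {
      first_n <- acc_order[[t]][seq_len(N)]
      th <- T_theta[first_n, , drop = FALSE]
      colnames(th) <- paste0("theta_", seq_len(nth))
      df <- data.frame(
        generation = t,
        proposal_id = ifelse(T_prelim[first_n], sprintf("g~%d", t), sprintf("g%d", t)),
        th,
        distance = T_dist[first_n],
        weight = weights_for(t, first_n),
        start_time = T_start[first_n],
        end_time = T_end[first_n],
        launch_index = first_n,
        stringsAsFactors = FALSE)
      pop_hat <- new_population(df, epsilon = eps[t], generation = t,
                                beta_rule = beta_rule)
      prelimProp[[t_next]] <<- build_preliminary_proposal(
        "prel", preliminary_pop = pop_hat, cfg = kernel)
    }
    invisible(NULL)
  }

  suppress_prelim <- function() {
    if (!sch$termination_prediction) return(FALSE)
    est <- NULL
    if (epsilon$kind == "quantile" && !is.null(epsilon$eps_min) &&
        G_acc[t_cur] > 0L) {
      est <- unname(stats::quantile(T_dist[acc_order[[t_cur]]], epsilon$q,
                                    type = 7))
    }
    predict_termination(t_cur, n_t, next_epsilon_estimate = est,
                        eps_min = epsilon$eps_min)
  }

  advance <- function(tau) {
    t <- t_cur
    populations[[t]] <<- finalize_pop(t)
    close_time[t] <<- tau
    if (t >= n_t) { done <<- TRUE; return(invisible(NULL)) }
    pop <- populations[[t]]
    e_next <- next_epsilon(epsilon, t + 1L,
                           prev_distances = pop$particles$distance,
                           prev_epsilon = eps[t])
    if (is.na(e_next) ||
        (!is.null(epsilon$eps_min) && eps[t] <= epsilon$eps_min)) {
      done <<- TRUE; return(invisible(NULL))
    }
    eps[t + 1L] <<- e_next
    t_cur <<- t + 1L
    if (sch$post_process_time > 0) clock <<- clock + sch$post_process_time
    # delayed acceptance evaluation of already-finished preliminary samples,
    # now that the common generation-t criterion is fixed
    for (i in pending[[t_cur]]) eval_task(i)
    pending[[t_cur]] <<- integer()
    invisible(NULL)
  }

  assign_work <- function() {
    for (wid in which(!w_busy)) {
      t <- t_cur
      if (stat) {
        if (G_assigned[t] < N) {
          G_assigned[t] <<- G_assigned[t] + 1L
          launch(wid, t, FALSE)
        }
      } else if (G_acc[t] < N) {
        launch(wid, t, FALSE)
      } else if (la && t < n_t && !suppress_prelim() &&
                 G_prelim[t + 1L] < cap_prelim) {
        ensure_prelim(t + 1L)
        launch(wid, t + 1L, TRUE)
      }
      # otherwise the worker idles until the next event
    }
    invisible(NULL)
  }

  # --- initial threshold ---
  if (epsilon$kind == "fixed") {
    eps[seq_len(n_t)] <- epsilon$values[seq_len(n_t)]
  } else {
    # pilot prior-predictive sample of size N calibrates epsilon_1
    pilot <- vapply(seq_len(N), function(i) {
      th <- as.numeric(rng_eval(rng, "prior", problem$prior$sample(1L)))
      y <- rng_eval(rng, "simulator", problem$model(th))
      problem$distance(y, problem$observed)
    }, numeric(1))
    eps[1L] <- next_epsilon(epsilon, 1L, prev_distances = pilot)
  }
  finalProp[[1L]] <- problem$prior

  assign_work()
  while (!done) {
    busy <- which(w_busy)
    if (!length(busy)) stop("internal error: scheduler deadlock")
    tau <- min(w_finish[busy])
    clock <- tau
    for (wid in busy[w_finish[busy] <= tau]) on_finish(wid)
    while (!done && G_acc[t_cur] >= N && G_inflight[t_cur] == 0L)
      advance(tau)
    if (done) break
    assign_work()
  }

  t_last <- max(which(!is.na(close_time)))
  wall <- close_time[t_last]
  used <- seq_len(ntask)
  busy_time <- sum(pmin(T_end[used], wall) - pmin(T_start[used], wall))
  idle_frac <- 1 - busy_time / (W * wall)

  pops <- populations[seq_len(t_last)]
  n_tilde <- vapply(pops, function(p) p$n_tilde, numeric(1))
  tasks <- data.frame(
    task = used,
    generation = T_gen[used],
    proposal_id = ifelse(T_prelim[used], sprintf("g~%d", T_gen[used]),
                         sprintf("g%d", T_gen[used])),
    worker = T_worker[used],
    start_time = T_start[used],
    end_time = T_end[used],
    distance = T_dist[used],
    accepted = T_acc[used],
    stringsAsFactors = FALSE)

  structure(list(
    populations = pops,
    epsilon = eps[seq_len(t_last)],
    n_tilde = n_tilde,
    n_tilde_frac = n_tilde / N,
    betas = lapply(pops, function(p) p$betas),
    ess = vapply(pops, population_ess, numeric(1)),
    wall_time = wall,
    idle_fraction = idle_frac,
    close_times = close_time[seq_len(t_last)],
    tasks = tasks,
    n_simulations = ntask,
    n_generations = t_last,
    strategy = strategy,
    seed = seed,
    config = list(problem = problem$name, scheduler = unclass(sch),
                  kernel = unclass(kernel), epsilon = unclass(epsilon),
                  beta_rule = beta_rule, seed = seed)),
    class = "abc_run")
}

#' @export
print.abc_run <- function(x, ...) {
  cat(sprintf(
    "<abc_run> %s: %d generations, N = %d, W = %d\n  wall-time %.2f s, idle %.1f%%, %d simulations\n  epsilon: %s\n  N~/N:    %s\n",
    x$strategy, x$n_generations, x$config$scheduler$population_size,
    x$config$scheduler$n_workers, x$wall_time, 100 * x$idle_fraction,
    x$n_simulations, paste(signif(x$epsilon, 3), collapse = " "),
    paste(signif(x$n_tilde_frac, 3), collapse = " ")))
  invisible(x)
}

#' Worker occupancy accounting
#'
#' Exact busy/idle accounting of the simulated worker pool: total busy time
#' is the integral of the occupancy timeline, the idle fraction is measured
#' against `n_workers * wall_time`.
#'
#' @param run An `abc_run`.
#' @return A list with `wall_time`, `busy_time`, `idle_time`,
#'   `idle_fraction`, and a per-worker data.frame `per_worker`.
#' @export
worker_occupancy <- function(run) {
  wall <- run$wall_time
  tk <- run$tasks
  dur <- pmin(tk$end_time, wall) - pmin(tk$start_time, wall)
  per_worker <- stats::aggregate(dur, by = list(worker = tk$worker), FUN = sum)
  names(per_worker)[2L] <- "busy_time"
  busy <- sum(dur)
  W <- run$config$scheduler$n_workers
  list(wall_time = wall, busy_time = busy,
       idle_time = W * wall - busy,
       idle_fraction = 1 - busy / (W * wall),
       per_worker = per_worker)
}
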