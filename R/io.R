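fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write and read population tables
#'
#' Populations serialize to CSV with one row per particle: generation,
#' proposal id, parameter components, distance, raw weight, subpopulation-
#' normalized weight, combined weight, and scheduling timestamps. Floats are
#' written with a full-precision representation so that
#' `read_population_csv(write_population_csv(x))` is lossless.
#'
#' @param populations A list of `abc_population` objects or an `abc_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(populations, path) {
  if (inherits(populations, "abc_run")) populations <- populations$populations
  if (inherits(populations, "abc_population")) populations <- list(populations)
  df <- do.call(rbind, lapply(populations, function(p) p$particles))
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(df), "proposal_id")
  for (j in num) df[[j]] <- as.numeric(df[[j]])
  df$generation <- as.integer(df$generation)
  df$launch_index <- as.integer(df$launch_index)
  df
}

#' Persist a run to a results directory
#'
#' Writes `populations.csv` (all generations), `events.csv` (the worker
#' timeline, one row per simulation), `summary.json` (wall-time, idle
#' fraction, per-generation epsilon, ESS, N~/N, betas) and `config.yaml`.
#'
#' @param run An `abc_run`.
#' @param dir Output directory.
#' @param force Overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, force = FALSE) {
  stopifnot(inherits(run, "abc_run"))
  if (dir.exists(dir) && !force)
    stop("output directory exists (use force = TRUE): ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_population_csv(run, file.path(dir, "populations.csv"))
  ev <- as.data.frame(lapply(run$tasks, fmt_full), stringsAsFactors = FALSE)
  names(ev) <- names(run$tasks)
  utils::write.table(ev, file.path(dir, "events.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  summ <- run_summary(run)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(run$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Summary statistics of a run
#'
#' @param run An `abc_run`.
#' @return Named list of the run's headline quantities.
#' @export
run_summary <- function(run) {
  list(strategy = run$strategy,
       seed = run$seed,
       n_generations = run$n_generations,
       wall_time = run$wall_time,
       idle_fraction = run$idle_fraction,
       n_simulations = run$n_simulations,
       epsilon = run$epsilon,
       ess = run$ess,
       n_tilde = run$n_tilde,
       n_tilde_frac = run$n_tilde_frac,
       betas = lapply(run$betas, as.list),
       close_times = run$close_times)
}

#' Reload a persisted run
#'
#' Reconstructs the particle tables and summary of a run written by
#' [write_run()]. The reload is lossless at full floating-point precision.
#'
#' @param dir Results directory.
#' @return A list with `populations` (data.frame), `events` (data.frame),
#'   `summary` (list) and `config` (list).
#' @export
read_run <- function(dir) {
  list(populations = read_population_csv(file.path(dir, "populations.csv")),
       events = {
         ev <- utils::read.csv(file.path(dir, "events.csv"),
                               stringsAsFactors = FALSE)
         for (j in c("start_time", "end_time", "distance"))
           ev[[j]] <- as.numeric(ev[[j]])
         ev$accepted <- as.logical(ev$accepted)
         ev
       },
       summary = jsonlite::read_json(file.path(dir, "summary.json"),
                                     simplifyVector = TRUE),
       config = yaml::read_yaml(file.path(dir, "config.yaml")))
}

parse_epsilon_config <- function(cfg) {
  if (inherits(cfg, "epsilon_schedule")) return(cfg)
  if (identical(cfg$kind, "fixed")) return(epsilon_fixed(unlist(cfg$values)))
  if (identical(cfg$kind, "quantile"))
    return(epsilon_quantile(q = cfg$q %||% 0.5, eps_min = cfg$eps_min))
  stop("epsilon config needs kind 'fixed' or 'quantile'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a replicate sweep over scheduling strategies
#'
#' Experiment driver: runs every strategy for `replicates` matched seeds
#' (replicate r of every strategy uses seed `seed + r - 1`, so strategies
#' are compared on matched randomness), optionally persists each run, and
#' aggregates wall-times, idle fractions, ESS and N~/N into one table.
#'
#' @param config Named list (or path to a YAML file) with entries `problem`
#'   (list: `id`, optional `params`), `strategies` (character vector), `n`,
#'   `workers`, `generations`, `epsilon` (list: `kind`, `values`/`q`),
#'   optional `kernel` (list: `scale_factor`, `jitter`), `seed`,
#'   `replicates`, optional `out` directory and `force`.
#' @return A data.frame, one row per (strategy, replicate), with the run
#'   summaries; attribute `"runs"` holds the `abc_run` objects.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  strategies <- unlist(config$strategies)
  if (length(strategies) == 0L) stop("empty strategy list")
  problem <- get_problem(config$problem$id, config$problem$params %||% list())
  epsilon <- parse_epsilon_config(config$epsilon %||%
                                    default_epsilon_schedule(config$problem$id))
  kern <- do.call(kernel_config, config$kernel %||% list())
  reps <- config$replicates %||% 1L
  seed0 <- config$seed %||% 1L
  out <- config$out
  if (!is.null(out) && dir.exists(out) && !isTRUE(config$force))
    stop("output directory exists (set force: true): ", out)
  rows <- list()
  runs <- list()
  for (s in strategies) {
    for (r in seq_len(reps)) {
      sch <- scheduler_config(strategy = s,
                              n_workers = config$workers,
                              population_size = config$n,
                              max_generations = config$generations %||% Inf)
      run <- abc_smc(problem, sch, epsilon, kern, seed = seed0 + r - 1L)
      key <- sprintf("%s_rep%d", s, r)
      runs[[key]] <- run
      if (!is.null(out)) write_run(run, file.path(out, key), force = TRUE)
      rows[[key]] <- data.frame(
        strategy = s, replicate = r, seed = seed0 + r - 1L,
        n_generations = run$n_generations,
        wall_time = run$wall_time,
        idle_fraction = run$idle_fraction,
        n_simulations = run$n_simulations,
        final_epsilon = run$epsilon[run$n_generations],
        final_ess = run$ess[run$n_generations],
        final_n_tilde_frac = run$n_tilde_frac[run$n_generations],
        stringsAsFactors = FALSE)
    }
  }
  agg <- do.call(rbind, rows)
  rownames(agg) <- NULL
  if (!is.null(out)) {
    aout <- as.data.frame(lapply(agg, fmt_full), stringsAsFactors = FALSE)
    names(aout) <- names(agg)
    utils::write.table(aout, file.path(out, "aggregate.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  }
  attr(agg, "runs") <- runs
  agg
}

#' Wall-time speed-up of one strategy over another
#'
#' `1 - mean(wall[a]) / mean(wall[b])` from an experiment table, e.g. the
#' speed-up of look-ahead over dynamic scheduling.
#'
#' @param agg Experiment table from [run_experiment()].
#' @param a,b Strategy names (speed-up of `a` over `b`).
#' @return Scalar speed-up fraction.
#' @export
aggregate_speedup <- function(agg, a = "la_past", b = "dyn") {
  wa <- agg$wall_time[agg$strategy == a]
  wb <- agg$wall_time[agg$strategy == b]
  if (!length(wa) || !length(wb)) stop("strategies not present in table")
  1 - mean(wa) / mean(wb)
}

#' Diagnostics report for a completed run
#'
#' @param run An `abc_run`.
#' @return A list of data.frames: `posterior` (combined-weight mean and sd
#'   per parameter of the final population), `generations` (epsilon, ESS,
#'   N~/N, beta of the preliminary subpopulation, acceptance counts per
#'   generation) and `occupancy` (wall/busy/idle accounting).
#' @export
diagnostics_report <- function(run) {
  stopifnot(inherits(run, "abc_run"))
  fin <- run$populations[[run$n_generations]]
  th <- population_theta(fin)
  w <- fin$particles$comb_weight
  mu <- colSums(th * w)
  sdv <- sqrt(pmax(colSums(th^2 * w) - mu^2, 0))
  posterior <- data.frame(parameter = colnames(th), mean = mu, sd = sdv,
                          row.names = NULL)
  generations <- data.frame(
    generation = seq_len(run$n_generations),
    epsilon = run$epsilon,
    ess = run$ess,
    n_tilde = run$n_tilde,
    n_tilde_frac = run$n_tilde_frac,
    beta_prelim = vapply(run$betas, function(b) {
      pre <- grepl("~", names(b), fixed = TRUE)
      if (any(pre)) unname(b[pre]) else 0
    }, numeric(1)),
    accepted = vapply(seq_len(run$n_generations), function(t)
      sum(run$tasks$generation == t & run$tasks$accepted %in% TRUE), numeric(1)),
    launched = vapply(seq_len(run$n_generations), function(t)
      sum(run$tasks$generation == t), numeric(1)))
  occ <- worker_occupancy(run)
  occupancy <- data.frame(wall_time = occ$wall_time, busy_time = occ$busy_time,
                          idle_time = occ$idle_time,
                          idle_fraction = occ$idle_fraction)
  list(posterior = posterior, generations = generations, occupancy = occupancy)
}

#' Worker-occupancy timeline plot
#'
#' Draws each simulation as a horizontal segment on its worker's row,
#' colored by generation (preliminary samples dashed), with generation close
#' times as vertical lines — the per-run occupancy picture that
#' distinguishes the scheduling strategies.
#'
#' @param run An `abc_run`.
#' @param ... Passed to [graphics::plot()].
#' @return The run, invisibly.
#' @export
plot_worker_timeline <- function(run, ...) {
  tk <- run$tasks
  W <- run$config$scheduler$n_workers
  cols <- grDevices::hcl.colors(max(tk$generation), "Dark 3")
  graphics::plot(NULL, xlim = c(0, run$wall_time), ylim = c(0.5, W + 0.5),
                 xlab = "simulated time [s]", ylab = "worker",
                 main = sprintf("%s: occupancy timeline", run$strategy), ...)
  pre <- grepl("~", tk$proposal_id, fixed = TRUE)
  graphics::segments(tk$start_time, tk$worker, pmin(tk$end_time, run$wall_time),
                     tk$worker, col = cols[tk$generation],
                     lty = ifelse(pre, 2L, 1L), lwd = 3)
  graphics::abline(v = run$close_times, col = "grey40")
  invisible(run)
}
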