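#' Acceptance-threshold schedules
#'
#' The sequence of thresholds `epsilon_t` is strictly decreasing over
#' generations. Two schedules are provided: a fixed, pre-defined list
#' (which also makes runs directly comparable across scheduling strategies),
#' and a quantile-adaptive rule taking `epsilon_t` as a quantile of the
#' previous generation's accepted distances.
#'
#' @param values Strictly decreasing vector of positive thresholds. The
#'   schedule terminates the run when exhausted.
#' @return An object of class `epsilon_schedule`.
#' @export
epsilon_fixed <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(values > 0),
            all(diff(values) < 0))
  structure(list(kind = "fixed", values = as.numeric(values)),
            class = "epsilon_schedule")
}

#' @rdname epsilon_fixed
#' @param q Quantile in `(0, 1)` of the previous generation's accepted
#'   distances (default 0.5; linear-interpolation quantile, type 7). The
#'   initial threshold is calibrated as the `q`-quantile of distances from a
#'   pilot prior sample of size N.
#' @param eps_min Optional positive floor: the run terminates once the
#'   realized threshold falls to or below it.
#' @export
epsilon_quantile <- function(q = 0.5, eps_min = NULL) {
  stopifnot(q > 0, q < 1)
  if (!is.null(eps_min)) stopifnot(eps_min > 0)
  structure(list(kind = "quantile", q = q, eps_min = eps_min),
            class = "epsilon_schedule")
}

#' @export
print.epsilon_schedule <- function(x, ...) {
  if (x$kind == "fixed")
    cat("<epsilon_schedule> fixed:", paste(signif(x$values, 4), collapse = " "), "\n")
  else
    cat(sprintf("<epsilon_schedule> quantile q = %g%s\n", x$q,
                if (!is.null(x$eps_min)) sprintf(", eps_min = %g", x$eps_min) else ""))
  invisible(x)
}

#' Next acceptance threshold
#'
#' For a fixed schedule, the t-th list entry (`NA` once exhausted, which
#' signals termination). For a quantile schedule, the `q`-quantile of the
#' previous generation's accepted distances; if that is not strictly below
#' the previous threshold (e.g. for degenerate constant distances), a guard
#' shrinks it to `0.99 * epsilon_{t-1}` so the realized sequence is always
#' strictly decreasing.
#'
#' @param schedule An `epsilon_schedule`.
#' @param t Generation index (`>= 1`).
#' @param prev_distances Accepted distances of generation `t - 1` (quantile
#'   schedule, `t >= 2`), or the pilot prior-sample distances for `t = 1`.
#' @param prev_epsilon Realized threshold of generation `t - 1`.
#' @return Scalar threshold, or `NA` for termination.
#' @examples
#' next_epsilon(epsilon_fixed(c(1, 0.5, 0.25)), 2)            # 0.5
#' next_epsilon(epsilon_quantile(0.5), 2, c(1, 2, 3, 4), 10)  # 2.5
#' @export
next_epsilon <- function(schedule, t, prev_distances = NULL,
                         prev_epsilon = NULL) {
  stopifnot(inherits(schedule, "epsilon_schedule"), t >= 1L)
  if (schedule$kind == "fixed") {
    if (t > length(schedule$values)) return(NA_real_)
    return(schedule$values[t])
  }
  if (is.null(prev_distances))
    stop("quantile schedule requires distances from the previous generation (or a pilot sample)")
  e <- unname(stats::quantile(prev_distances, schedule$q, type = 7))
  if (!is.null(prev_epsilon) && e >= prev_epsilon) e <- 0.99 * prev_epsilon
  if (e <= 0) stop("quantile threshold is not positive")
  e
}

#' Predict whether the run terminates after the current generation
#'
#' Look-ahead scheduling suppresses preliminary sampling when no further
#' generation will run. Two simple rules are used: the current generation is
#' the last one (`t >= max_generations`), or the running quantile estimate
#' of the next threshold is already at or below the configured floor.
#'
#' @param t Current generation index.
#' @param max_generations Total number of generations.
#' @param next_epsilon_estimate Optional running estimate of the next
#'   threshold (e.g. the quantile of the distances accepted so far).
#' @param eps_min Optional threshold floor.
#' @return Logical: `TRUE` to suppress preliminary sampling.
#' @export
predict_termination <- function(t, max_generations,
                                next_epsilon_estimate = NULL, eps_min = NULL) {
  if (t >= max_generations) return(TRUE)
  if (!is.null(eps_min) && !is.null(next_epsilon_estimate) &&
      is.finite(next_epsilon_estimate) && next_epsilon_estimate <= eps_min)
    return(TRUE)
  FALSE
}
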