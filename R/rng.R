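#' Named random-number substreams
#'
#' Creates a set of independent, named RNG substreams from one master seed.
#' Each statistical component of a run (prior draws, kernel perturbations,
#' model noise, simulated durations, scheduler decisions) draws from its own
#' stream. Because the streams are isolated, the interleaving of scheduler
#' events cannot perturb the sequence of statistical draws, and a run is
#' reproducible bit-for-bit from `(seed, config)` on the simulated backend.
#'
#' @param seed Integer master seed (kept below `2^31`).
#' @param streams Character vector of substream names.
#' @return An object of class `rng_streams`: an environment holding one saved
#'   R RNG state per stream.
#' @examples
#' r <- rng_streams(1)
#' a <- rng_eval(r, "prior", rnorm(3))
#' b <- rng_eval(r, "simulator", rnorm(3))
#' # the prior stream continues where it left off, untouched by "simulator"
#' a2 <- rng_eval(r, "prior", rnorm(3))
#' @export
rng_streams <- function(seed,
                        streams = c("prior", "perturbation", "simulator",
                                    "durations", "scheduler")) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  seed <- as.integer(seed %% (.Machine$integer.max - 1L))
  e <- new.env(parent = emptyenv())
  e$master <- seed
  e$states <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(streams))
  for (i in seq_along(streams)) {
    set.seed(subseeds[i])
    assign(streams[i], get(".Random.seed", globalenv()), envir = e$states)
  }
  class(e) <- "rng_streams"
  e
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate an expression under a named substream
#'
#' Swaps in the saved RNG state of `stream`, evaluates `expr`, saves the
#' advanced state back, and restores the caller's RNG state.
#'
#' @param rng An [rng_streams] object.
#' @param stream Substream name.
#' @param expr Expression to evaluate (drawing from the R RNG).
#' @return The value of `expr`.
#' @export
rng_eval <- function(rng, stream, expr) {
  st <- get0(stream, rng$states, inherits = FALSE)
  if (is.null(st)) stop("unknown RNG stream: ", stream)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", st, envir = globalenv())
  on.exit({
    assign(stream, get(".Random.seed", globalenv()), envir = rng$states)
    restore_seed(old)
  }, add = TRUE)
  expr
}

#' @export
print.rng_streams <- function(x, ...) {
  cat("<rng_streams> master seed", x$master, "streams:",
      paste(ls(x$states), collapse = ", "), "\n")
  invisible(x)
}
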