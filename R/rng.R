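#' Seeded random stream with named substreams
#'
#' Reproducibility backbone of the simulator. A single session seed is
#' expanded into independent named substreams (arrivals, discharge,
#' multiplier, tiebreak, policy) so that, e.g., changing `arrivals_per_day`
#' does not perturb the discharge draws. Each substream carries its own
#' Mersenne-Twister state; draws from one never advance another.
#'
#' The object is an environment (mutable handle): drawing advances the named
#' substream in place, which is what lets the engine thread one stream through
#' the whole session.
#'
#' @param seed Integer master seed.
#' @param streams Character vector of substream names.
#' @return A `random_stream` object.
#' @export
random_stream <- function(seed,
                          streams = c("arrivals", "discharge", "multiplier",
                                      "tiebreak", "policy")) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  rs <- new.env(parent = emptyenv())
  rs$seed <- as.integer(seed)
  rs$states <- new.env(parent = emptyenv())
  # derive substream seeds deterministically from the master seed
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(rs$seed, kind = "Mersenne-Twister")
  sub_seeds <- sample.int(.Machine$integer.max, length(streams))
  for (i in seq_along(streams)) {
    set.seed(sub_seeds[i], kind = "Mersenne-Twister")
    assign(streams[i], get(".Random.seed", envir = globalenv()), envir = rs$states)
  }
  class(rs) <- "random_stream"
  rs
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Draw from a named substream
#'
#' Runs `expr` with the substream's RNG state installed, then saves the
#' advanced state back into the stream. The caller's global RNG state is
#' untouched.
#'
#' @param rs A `random_stream`.
#' @param stream Substream name.
#' @param expr Expression performing the draws (e.g. `runif(1)`).
#' @return The value of `expr`.
#' @export
rs_draw <- function(rs, stream, expr) {
  stopifnot(inherits(rs, "random_stream"))
  if (!exists(stream, envir = rs$states, inherits = FALSE)) {
    stop(sprintf("unknown substream '%s'", stream), call. = FALSE)
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  assign(".Random.seed", get(stream, envir = rs$states), envir = globalenv())
  out <- force(expr)
  assign(stream, get(".Random.seed", envir = globalenv()), envir = rs$states)
  out
}

#' @export
print.random_stream <- function(x, ...) {
  cat(sprintf("<random_stream> seed %d, substreams: %s\n", x$seed,
              paste(ls(x$states), collapse = ", ")))
  invisible(x)
}
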