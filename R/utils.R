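#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state, restoring the caller's state on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Expands one global seed into per-stage, per-subject seeds through a fixed
#' linear-congruential scheme, so any subject's data can be regenerated in
#' isolation without replaying the whole stream.  The result is always a
#' positive integer below 2^31 - 1.
#'
#' @param seed Integer parent seed.
#' @param stage Integer stage tag (each pipeline stage uses its own tag).
#' @param index Integer index within the stage (e.g. subject number).
#' @return A single integer seed.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + as.double(stage) * 100003 + as.double(index)
  as.integer(s %% m) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
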