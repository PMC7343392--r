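# Internal helpers shared across modules.

#' Derive a reproducible child seed from a global seed and a set of labels
#'
#' One global seed expands deterministically into per-subject / per-stage /
#' per-stream child seeds so that any subset of a simulated study can be
#' regenerated on its own. The expansion is a simple counter/label hash kept
#' strictly below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric labels identifying the stream
#'   (e.g. subject id, stage, `"beats"`).
#' @return A single integer seed.
#' @export
child_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  bytes <- utf8ToInt(labels)
  m <- 2147483647 # 2^31 - 1 (Mersenne prime), keeps seeds in integer range
  h <- as.numeric(seed) %% m
  for (b in bytes) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Run code under a local RNG state (does not disturb the caller's stream).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "lcarousal_config_error")
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)
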