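#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats prcomp rnorm runif var
#' @importFrom utils head
NULL

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "omicsgsn_validation_error", ...)
}

abort_io <- function(message, ...) {
  rlang::abort(message, class = "omicsgsn_io_error", ...)
}

abort_parse <- function(message, ...) {
  rlang::abort(message, class = "omicsgsn_parse_error", ...)
}

abort_runtime <- function(message, ...) {
  rlang::abort(message, class = "omicsgsn_runtime_error", ...)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-stage seed from one global seed
#'
#' One pipeline-level seed fans out deterministically to independent per-stage
#' seeds so that changing one stage's stochastic behaviour never perturbs
#' another's. The derivation is a fixed integer hash of the stage name mixed
#' with the global seed; it is stable across platforms and R sessions.
#'
#' @param global_seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"embed"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  s <- (abs(as.numeric(global_seed)) * 69069 + h) %% 2147483646
  as.integer(s) + 1L
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
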