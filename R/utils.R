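# Internal helpers: condition constructors and scoped RNG.

abort_config <- function(msg) {
  stop(errorCondition(msg, class = "wpfx_config_error"))
}

abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("wpfx_invalid_input",
                                     "wpfx_config_error")))
}

abort_numeric <- function(msg) {
  stop(errorCondition(msg, class = "wpfx_numeric_error"))
}

abort_singular <- function(msg, cond_estimate = NA_real_) {
  stop(errorCondition(msg, cond_estimate = cond_estimate,
                      class = c("wpfx_singular_system",
                                "wpfx_numeric_error")))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a master seed
#'
#' A single master seed governs every stochastic stage of an experiment
#' (crystal-size sampling, fixture atoms, optional noise). Each stage derives
#' its own sub-seed by hashing the stage name, so stages are decoupled while
#' the whole pipeline stays reproducible from one integer.
#'
#' @param seed master seed (integer).
#' @param stage character stage name, e.g. `"sizes"` or `"atoms"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
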