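# internal helpers shared across modules

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL runs under the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# round half away from zero (annotation index rescaling; R's round() is half-even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

as_signal_matrix <- function(signal) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  storage.mode(signal) <- "double"
  signal
}
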