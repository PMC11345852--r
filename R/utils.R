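# shared internal helpers

# Seed the RNG for the calling function's scope and restore it afterwards.
local_rng <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
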