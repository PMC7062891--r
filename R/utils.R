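# internal helpers shared across modules

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 so it is always a valid input to set.seed().
derive_seed <- function(master, index) {
  m <- 2147483629
  a <- ((as.numeric(master) %% m) * 48271) %% m
  b <- (1103515245 * (as.numeric(index) %% 1024) + as.numeric(index)) %% m
  as.integer((a + b) %% m)
}

# Evaluate a function under a local RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tdbold <- function(...) stop(..., call. = FALSE)
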