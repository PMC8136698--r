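# Internal condition helpers. All package errors inherit from "dbg_error" and
# carry a specific subclass so callers (and the CLI) can map them to exit codes.

dbg_stop <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "dbg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
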