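# Internal helpers shared across modules.

# Raise a classed condition so callers can distinguish failure modes with
# tryCatch(..., prepscore_missing_file = ...) etc.
stop_named <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "prepscore_error")))
}

warn_named <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "prepscore_warning")))
}

# Deterministic 31-bit polynomial hash of a string; used to derive per-case
# sampling streams so batch order cannot affect any single case.
hash_string <- function(x) {
  if (is.null(x) || !nzchar(x)) return(0L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Combine a user seed with a per-object hash into a valid 32-bit seed.
derive_seed <- function(seed, label = NULL) {
  as.integer((as.numeric(seed) %% 2147483647 + hash_string(label)) %% 2147483647)
}

# Run expr with a private RNG state: seeds locally, restores the caller's
# .Random.seed on exit so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
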