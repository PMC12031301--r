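# Internal helpers shared across modules.

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All user-facing stochastic operations funnel
# through this so that a seed argument fully determines the result without
# disturbing the session RNG.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a master seed, kept inside the 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 12347L) %% 2147483629)
}

stop_typed <- function(class, msg, ...) {
  stop(structure(class = c(class, "cwqsar_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
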