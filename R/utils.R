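# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never disturb the global
# stream.
with_private_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# tangent of an angle given in degrees (keratometric powers enter the Hoffer Q
# ELP model through degree-based tangents)
tan_deg <- function(x) tan(x * pi / 180)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_iol <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "iolpred_error")))
}
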