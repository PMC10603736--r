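# Deterministic seed derivation.
#
# Every source of randomness in the package hangs off one user seed; child
# streams are derived by hashing the seed together with string tags (domain,
# class name, purpose), so adding a class or a head never perturbs the draws
# of the others.

# FNV-1a over the tag bytes, folded into [0, 2^31 - 2]; pure integer-double
# arithmetic so it is identical on every platform.
child_seed <- function(seed, ...) {
  tags <- paste(c(format(seed, scientific = FALSE), ...), collapse = "\r")
  bytes <- utf8ToInt(tags)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
}
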