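# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` means "use the current stream" so composite
# generators can fan out to sub-generators under one outer seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) with max-subtraction; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Two-sided normal p-value from a z-score, safe for |z| = 0 and very large |z|.
z_to_p <- function(z) {
  2 * pnorm(-abs(z))
}

# |z| implied by a two-sided p-value.
p_to_z <- function(p) {
  -qnorm(p / 2)
}

assert_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single probability in %s0, 1%s.",
                  name, if (open_left) "(" else "[",
                  if (open_right) ")" else "]"),
          class = "mrcoco_parameter_error")
  }
  invisible(x)
}

param_error <- function(msg) {
  abort(msg, class = "mrcoco_parameter_error")
}

data_error <- function(msg) {
  abort(msg, class = "mrcoco_data_error")
}
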