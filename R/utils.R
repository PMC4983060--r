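# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points route through this
# so that a single integer seed fully determines their output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
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
  }
  force(code)
}

# Derive a child seed from a master seed; kept well below .Machine$integer.max.
spawn_seed <- function(seed, offset) {
  (as.integer(seed) * 69069L + as.integer(offset)) %% 2147480009L
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("configuration error: `%s` must be a probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("configuration error: `%s` must be an integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Last-observation-carried-forward on a vector already sorted by
# (subject, cycle). `first_of_group` marks each subject's baseline row, which
# is guaranteed non-missing upstream; carried values never cross subjects.
locf_vec <- function(x, first_of_group) {
  if (any(is.na(x[first_of_group]))) {
    stop("carry-forward requires complete baseline values; ",
         "subjects with missing baseline predictors must be excluded upstream",
         call. = FALSE)
  }
  idx <- seq_along(x)
  idx[is.na(x)] <- 0L
  x[cummax(idx)]
}
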