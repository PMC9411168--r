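# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Each stochastic stage (and each kinase's permutation stream) draws from
#' its own RNG stream, derived deterministically from the master seed and a
#' stage/kinase key. Adding a stage or reordering kinases therefore never
#' perturbs the random numbers any other stage sees.
#'
#' The key is hashed with a small polynomial rolling hash over its UTF-8
#' bytes and folded into the master seed modulo 2^31 - 1, keeping the result
#' in the portable 32-bit integer range.
#'
#' @param seed Master seed (single non-negative integer).
#' @param key Character scalar naming the stream.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1
  h <- seed %% m
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# RNG state afterwards.
with_stream <- function(seed, key, expr) {
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
  set.seed(derive_seed(seed, key))
  force(expr)
}

# Check that `df` has all columns in `cols`; abort naming the missing ones.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Scalar validators used by configuration constructors; all abort with the
# offending field name so errors are actionable.
check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", field, format(min)))
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  field, format(min), format(max)))
  }
  as.numeric(x)
}

# Unbiased per-row variance of a numeric matrix (n - 1 denominator).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) {
    return(rep(NA_real_, nrow(x)))
  }
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
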