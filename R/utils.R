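# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying inside
# the 32-bit integer range R requires of set.seed().
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 7919) %% 2147483647
}

stop_dims <- function(what, expected, got) {
  stop(sprintf("%s: expected length/dim %s, got %s", what,
               paste(expected, collapse = "x"), paste(got, collapse = "x")),
       call. = FALSE)
}

# Coerce a vector to a 1-row matrix, leave matrices untouched.
as_row_matrix <- function(x, n_cols, what = "input") {
  if (is.matrix(x)) {
    if (ncol(x) != n_cols) stop_dims(what, n_cols, ncol(x))
    return(x)
  }
  if (length(x) != n_cols) stop_dims(what, n_cols, length(x))
  matrix(x, nrow = 1L)
}
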