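# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the global stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, min = min)
  if (x != round(x)) abort(sprintf("`%s` must be a whole number.", name))
  invisible(as.integer(x))
}

# Coerce a feature input (matrix, or data frame of numeric columns) to a
# numeric subjects x features matrix, keeping dimnames.
as_feature_matrix <- function(x, arg = "features") {
  if (is.data.frame(x)) {
    id_col <- intersect("subject_id", names(x))
    ids <- if (length(id_col)) as.character(x[[id_col]]) else rownames(x)
    x <- as.matrix(x[setdiff(names(x), id_col)])
    if (!is.null(ids)) rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (subjects x features).", arg))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", arg))
  x
}

# All-permutations generator for small n (used by the exhaustive
# permutation test); returns a matrix with one permutation per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}
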