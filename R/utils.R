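# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All exported generators take an explicit `seed`; NULL uses the global RNG.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; keeps values < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7907 * as.double(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split equal-width aligned strings into a character matrix (rows = sequences).
# Passes an existing matrix through unchanged.
aln_to_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stopifnot(length(unique(nchar(aln))) == 1L)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

matrix_to_aln <- function(m) {
  out <- apply(m, 1L, paste0, collapse = "")
  names(out) <- rownames(m)
  out
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
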