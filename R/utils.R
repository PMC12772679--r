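# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps package randomness out of user code.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Euclidean norms of the rows of an n x 3 matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))

# Format numbers for text fixtures: shortest plain-decimal representation
# that parses back to the identical double (15 digits when lossless, 17
# otherwise), so save/load round-trips are bit-exact.
formatCoord <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) {
      s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }
    s
  }, character(1))
}

# Deterministic stratified fold assignment: returns integer fold id per row.
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
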