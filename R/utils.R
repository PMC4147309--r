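# Internal helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# n random DNA sequences of the given lengths (recycled), guaranteed
# distinct from each other and from `avoid`.
randomSequences <- function(n, lengths, avoid = character()) {
  lengths <- rep_len(lengths, n)
  out <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (s in avoid) assign(s, TRUE, envir = seen)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE),
                 collapse = "")
      if (!exists(s, envir = seen, inherits = FALSE)) break
    }
    assign(s, TRUE, envir = seen)
    out[i] <- s
  }
  out
}

# Hamming distance between equal-length strings (vectorized over x).
hammingDist <- function(x, y) {
  vapply(x, function(s) {
    a <- charToRaw(s); b <- charToRaw(y)
    if (length(a) != length(b)) return(NA_integer_)
    sum(a != b)
  }, integer(1), USE.NAMES = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
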