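# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
withSeed <- function(seed, code) {
  seed <- as.integer(seed)  # force now: the promise may consume RNG draws
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; kept below 2^31 - 1 so it is always a
# valid R integer seed.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729 + 13) %%
               2147483629)
}

# Connectivity of a non-negative symmetric weight matrix, by breadth-first
# search on the positive entries. Used in validity methods (cheap, base R).
adjacencyConnected <- function(w) {
  n <- nrow(w)
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

isSymmetricMatrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Project a symmetric matrix to the nearest correlation-like PSD matrix:
# clip negative eigenvalues, restore the unit diagonal.
nearestPsdCorrelation <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
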