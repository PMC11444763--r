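# Internal helpers shared across modules.

# Gas constant in kcal mol^-1 K^-1.
.RGAS <- 1.987e-3

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All exported stochastic operations route
# their randomness through this so no call leaks global RNG state.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# hex <-> bit helpers for the fingerprint sidecar format
# (one line per compound: id<TAB>hex; 4 bits per hex character, MSB first).
hexToBits <- function(hex) {
  chars <- strsplit(tolower(hex), "")[[1]]
  vals <- strtoi(chars, base = 16L)
  if (anyNA(vals)) stop("invalid hex fingerprint string: ", hex)
  bits <- vapply(vals, function(v) {
    as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L)))
  }, logical(4))
  as.vector(bits)
}

bitsToHex <- function(bits) {
  bits <- as.logical(bits)
  if (length(bits) %% 4L != 0L) {
    bits <- c(bits, rep(FALSE, 4L - length(bits) %% 4L))
  }
  m <- matrix(as.integer(bits), nrow = 4L)
  vals <- colSums(m * c(8L, 4L, 2L, 1L))
  paste(format.hexmode(vals), collapse = "")
}

# Euclidean distance matrix between the rows of two n x 3 matrices.
crossDist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
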