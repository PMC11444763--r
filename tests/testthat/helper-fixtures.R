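# Shared in-code fixtures for the test suite.

# Tiny library with hand-set predictions for selection tests.
predictedLibrary <- function(ids = c("A", "B", "C"),
                             dg = c(-11, -10, -9.5)) {
  lib <- CompoundLibrary(data.frame(id = ids))
  dgPred(lib) <- dg
  lib
}

# Library with a planted 10-member fingerprint cluster: a 32-bit shared
# mask (bits 1:32 of 64) plus one private bit per member, so every
# within-cluster pair has Tanimoto 32/34 ~ 0.94. Five background
# compounds live on disjoint bits.
plantedClusterLibrary <- function() {
  fp <- matrix(FALSE, nrow = 15L, ncol = 64L)
  for (i in 1:10) fp[i, c(1:32, 32L + i)] <- TRUE
  for (j in 1:5) fp[10L + j, c(45L + j, 50L + j)] <- TRUE
  ids <- c(sprintf("CL%02d", 1:10), sprintf("BG%02d", 1:5))
  CompoundLibrary(data.frame(id = ids), fingerprints = fp)
}

# Noise-free linear world: dg_exp is exactly linear in the descriptors.
noiselessLibrary <- function(n = 120L, d = 5L, seed = 11L) {
  makeLibrary(nScaffolds = 6L, nPerScaffold = n %/% 6L, featureDim = d,
              labelNoiseSd = 0, seed = seed)
}

# A constant-energy trace pair whose LIE estimate is exactly `dg`.
constantTracePair <- function(dg, replica = 1L, params = lieParameters(),
                              n = 10L) {
  vdw_b <- (dg - params@gamma) / params@alpha
  times <- seq(0, by = 1, length.out = n)
  list(energyTrace(times, rep(vdw_b, n), rep(0, n), "bound", replica),
       energyTrace(times, rep(0, n), rep(0, n), "unbound", replica))
}
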