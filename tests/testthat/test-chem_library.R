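test_that("compound tables read row-for-row with activity parsing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,activity_value,activity_unit,activity_kind",
               "C1,CCO,1000,nM,Ki",
               "C2,CCN,not-a-number,nM,Ki",
               "C3,CCC,5,uM,IC50"), f)
  lib <- readCompoundTable(f)
  expect_equal(length(lib), 3L)
  expect_equal(compoundIds(lib), c("C1", "C2", "C3"))  # row order kept
  cmp <- compounds(lib)
  expect_equal(cmp$activity_value[1], 1000)
  expect_equal(cmp$activity_unit[1], "nM")
  expect_equal(cmp$activity_kind[1], "Ki")
  # unparseable activity is dropped, the row is not
  expect_true(is.na(cmp$activity_value[2]))
  expect_equal(cmp$activity_kind[3], "IC50")
})

test_that("compound table structural errors are hard", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "C1,CCO", "C1,CCN"), f)
  expect_error(readCompoundTable(f), "C1")
  writeLines(c("smiles", "CCO"), f)
  expect_error(readCompoundTable(f), "id")
})

test_that("fingerprint sidecar round-trips through hex encoding", {
  gen <- makeLibrary(nScaffolds = 3L, nPerScaffold = 4L, fpBits = 64L,
                     seed = 5L)
  f <- withr::local_tempfile(fileext = ".fp")
  writeFingerprintSidecar(gen$library, f)
  stripped <- gen$library
  stripped@fingerprints <- matrix(logical(0), nrow = length(stripped),
                                  ncol = 0)
  back <- readFingerprintSidecar(stripped, f)
  expect_identical(fingerprints(back), fingerprints(gen$library))
})

test_that("tanimoto handles identity, disjoint, overlap and edge cases", {
  a <- c(rep(TRUE, 3), rep(FALSE, 5))
  expect_equal(tanimoto(a, a), 1)
  b <- c(rep(FALSE, 3), rep(TRUE, 3), FALSE, FALSE)
  expect_equal(tanimoto(a, b), 0)
  x <- rep(FALSE, 8); x[1:3] <- TRUE
  y <- rep(FALSE, 8); y[2:4] <- TRUE
  expect_equal(tanimoto(x, y), 0.5)
  expect_equal(tanimoto(rep(FALSE, 4), rep(FALSE, 4)), 1)  # both empty
  expect_error(tanimoto(c(TRUE, FALSE), c(TRUE, FALSE, TRUE)), "equal bit")
})

test_that("tanimoto is symmetric with unit diagonal on random bitsets", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(32) < 0.3
    b <- runif(32) < 0.3
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, a), 1)
  }
})

test_that("neighbor search recovers a planted cluster, excluding the seed", {
  lib <- plantedClusterLibrary()
  fp <- fingerprints(lib)
  # brute-force: every within-cluster pair clears the 0.9 floor
  for (i in 1:10) for (j in 1:10) {
    expect_gte(tanimoto(fp[i, ], fp[j, ]), 0.9)
  }
  hits <- neighborSearch(lib, "CL01", simCutoff = 0.9)
  expect_equal(compoundIds(hits), sprintf("CL%02d", 2:10))
})

test_that("neighbor search is order-invariant and monotone in cutoff", {
  lib <- plantedClusterLibrary()
  shuffled <- lib[rev(seq_len(length(lib)))]
  expect_identical(compoundIds(neighborSearch(lib, "CL03", 0.9)),
                   compoundIds(neighborSearch(shuffled, "CL03", 0.9)))
  loose <- compoundIds(neighborSearch(lib, "CL01", 0.2))
  tight <- compoundIds(neighborSearch(lib, "CL01", 0.95))
  expect_true(all(tight %in% loose))
  # degenerate cutoff: every non-seed record is a neighbor
  all_hits <- neighborSearch(lib, "CL01", 0)
  expect_equal(length(all_hits), length(lib) - 1L)
  expect_false("CL01" %in% compoundIds(all_hits))
})

test_that("neighbor search rejects invalid cutoffs and empty seeds", {
  lib <- plantedClusterLibrary()
  expect_error(neighborSearch(lib, "CL01", 1.0001), "\\[0, 1\\]")
  expect_error(neighborSearch(lib, "CL01", -0.1), "\\[0, 1\\]")
  expect_error(neighborSearch(lib, lib[integer(0)], 0.9), "empty")
  seeds_bad <- CompoundLibrary(data.frame(id = "Z"),
                               fingerprints = matrix(TRUE, 1, 16))
  expect_error(neighborSearch(lib, seeds_bad, 0.9), "incompatible")
})
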