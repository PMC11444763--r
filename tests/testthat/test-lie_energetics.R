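test_that("XVG reading honors metadata, units and monotone time", {
  f <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@    title \"Energy\"",
               "@ s0 legend \"LJ (SR)\"", "@ s1 legend \"Coul (SR)\"",
               "0.0 4.184 8.368", "1.0 4.184 8.368", "2.0 4.184 8.368"), f)
  tr <- readXVG(f, state = "bound", sourceUnits = "kJ/mol")
  expect_equal(tr@vdw, rep(1, 3))  # 4.184 kJ/mol = 1 kcal/mol
  expect_equal(tr@cou, rep(2, 3))
  # legends win over column order: swap them
  writeLines(c("@ s0 legend \"Coul (SR)\"", "@ s1 legend \"LJ (SR)\"",
               "0.0 8.368 4.184", "1.0 8.368 4.184"), f)
  tr2 <- readXVG(f, state = "bound", sourceUnits = "kJ/mol")
  expect_equal(tr2@vdw, rep(1, 2))
  # comments-only file
  writeLines(c("# only", "@ metadata"), f)
  expect_error(readXVG(f, "bound"), "fewer than 2")
  # non-monotone times
  writeLines(c("0.0 1 1", "0.0 1 1"), f)
  expect_error(readXVG(f, "bound", columns = c(vdw = 1, cou = 2)),
               "increasing")
  # no legends and no fallback mapping
  writeLines(c("0.0 1 1", "1.0 1 1"), f)
  expect_error(readXVG(f, "bound"), "columns")
})

test_that("XVG write/read round-trips a synthetic trace", {
  gen <- makeEnergyTraces(nFrames = 50L, nReplicas = 1L, seed = 8L)
  tr <- gen$traces[[1]]
  f <- withr::local_tempfile(fileext = ".xvg")
  writeXVG(tr, f)
  back <- readXVG(f, state = tr@state, replica = tr@replica,
                  sourceUnits = "kcal/mol")
  expect_equal(back@vdw, tr@vdw, tolerance = 1e-10)
  expect_equal(back@cou, tr@cou, tolerance = 1e-10)
  expect_equal(back@times, tr@times, tolerance = 1e-10)
})

test_that("trace means respect the equilibration discard window", {
  tr <- energyTrace(0:3, c(0, 0, 10, 10), rep(5, 4), "bound")
  expect_equal(traceMean(tr, 0.5), c(vdw = 10, cou = 5))
  expect_equal(traceMean(tr, 0), c(vdw = 5, cou = 5))
  const <- energyTrace(0:9, rep(-3, 10), rep(-3, 10), "unbound")
  expect_equal(traceMean(const, 0.7), c(vdw = -3, cou = -3))
  expect_error(traceMean(tr, 1), "\\[0, 1\\)")
})

test_that("autocorrelated trace means concentrate at the stationary mean", {
  gen <- makeEnergyTraces(trueMeans = c(vdw_b = -50, cou_b = -50,
                                        vdw_u = 0, cou_u = 0),
                          marginalSd = 3, tau = 5, dt = 2,
                          nFrames = 25000L, nReplicas = 1L, seed = 44L)
  m <- traceMean(gen$traces[[1]], 0.2)
  # AR(1) sample-mean sd: sd * sqrt((1+phi)/((1-phi) n)), phi = exp(-2/5)
  phi <- exp(-2 / 5)
  se <- 3 * sqrt((1 + phi) / ((1 - phi) * 20000))
  expect_lt(abs(m[["vdw"]] - (-50)), 3 * se)
  expect_lt(abs(m[["cou"]] - (-50)), 3 * se)
})

test_that("the LIE combination reproduces printed-parameter arithmetic", {
  expect_equal(lieEstimate(c(-30, -20), c(-30, -20)), -5.88)
  expect_equal(lieEstimate(c(-10, -5), c(0, 0)),
               0.288 * (-10) + (-0.049) * (-5) - 5.88)  # -8.515
  expect_equal(lieEstimate(c(1, 0), c(0, 0)), -5.592)
  # linearity in the vdW difference
  p <- lieParameters()
  d1 <- lieEstimate(c(1, 0), c(0, 0), p) - lieEstimate(c(0, 0), c(0, 0), p)
  d2 <- lieEstimate(c(2, 0), c(0, 0), p) - lieEstimate(c(1, 0), c(0, 0), p)
  expect_equal(d1, d2)
  expect_error(lieEstimate(c(NA, 0), c(0, 0)), "finite")
})

test_that("estimates are invariant to frame order and time rescaling", {
  gen <- makeEnergyTraces(nFrames = 200L, nReplicas = 1L, seed = 3L)
  tr <- gen$traces[[1]]
  scaled <- energyTrace(tr@times * 10, tr@vdw, tr@cou, tr@state, tr@replica)
  expect_equal(traceMean(scaled, 0.2), traceMean(tr, 0.2))
  perm <- sample(length(tr@times))
  # means over the full trace ignore order entirely
  shuffled <- energyTrace(sort(tr@times), tr@vdw[perm], tr@cou[perm],
                          tr@state, tr@replica)
  expect_equal(traceMean(shuffled, 0), traceMean(tr, 0))
})

test_that("replica aggregation gives mean, SEM and the n = 1 flag", {
  traces <- c(constantTracePair(-10, replica = 1L),
              constantTracePair(-11, replica = 2L))
  est <- lieWithUncertainty(traces)
  expect_equal(est@dg, -10.5)
  expect_equal(est@sem, 0.5)  # sd(c(-10,-11))/sqrt(2)
  expect_equal(est@nReplicas, 2L)
  expect_equal(sort(est@perReplica), c(-11, -10))
  single <- lieWithUncertainty(constantTracePair(-9))
  expect_equal(single@sem, 0)
  expect_equal(single@nReplicas, 1L)
  expect_output(show(single), "n = 1")
})

test_that("replica pairing is validated; shared unbound needs the flag", {
  pair1 <- constantTracePair(-10, replica = 1L)
  bound2 <- constantTracePair(-11, replica = 2L)[[1]]
  expect_error(lieWithUncertainty(c(pair1, list(bound2))), "mismatched")
  est <- lieWithUncertainty(c(pair1, list(bound2)), sharedUnbound = TRUE)
  expect_equal(est@nReplicas, 2L)
  expect_equal(est@dg, -10.5)
  expect_error(lieWithUncertainty(c(pair1, pair1)), "duplicate")
})

test_that("pooled aggregation weights frames, not replicas", {
  p1 <- constantTracePair(-10, replica = 1L, n = 10L)
  p2 <- constantTracePair(-12, replica = 2L, n = 40L)
  pooled <- lieWithUncertainty(c(p1, p2), pooled = TRUE, equilFraction = 0)
  averaged <- lieWithUncertainty(c(p1, p2), equilFraction = 0)
  expect_equal(averaged@dg, -11)
  expect_gt(averaged@dg, pooled@dg)  # pooling leans toward the longer run
})

test_that("replica SEMs are honestly calibrated against the analytic value", {
  # (dg - truth)/sem over n = 4 replicas is Student-t with 3 df, so the
  # correct >= 99% interval uses qt(0.995, 3), not the Gaussian factor 3
  tcrit <- qt(0.995, df = 3)
  covered <- vapply(1:10, function(s) {
    gen <- makeEnergyTraces(nFrames = 2000L, nReplicas = 4L, seed = s)
    est <- lieWithUncertainty(gen$traces)
    abs(est@dg - gen$analyticDg) <= tcrit * est@sem
  }, logical(1))
  expect_gte(sum(covered), 9L)
  # and the estimates themselves sit near the truth on the energy scale
  gen <- makeEnergyTraces(nFrames = 2000L, nReplicas = 4L, seed = 101L)
  est <- lieWithUncertainty(gen$traces)
  expect_lt(abs(est@dg - gen$analyticDg), 0.5)
})
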