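# A minimal donor-hydrogen-acceptor system: receptor N-H, ligand O.
hbFrame <- function(acceptorPos) {
  atoms <- data.frame(name = c("N", "H", "O1"),
                      resname = c("ALA", "ALA", "LIG"),
                      resno = c(1L, 1L, 999L), chain = c("A", "A", "X"),
                      element = c("N", "H", "O"), stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), acceptorPos)
  contactTrajectory(atoms, coords, c(FALSE, FALSE, TRUE))
}

test_that("hydrogen bonds require both the distance and the angle gate", {
  hb <- detectHbonds(hbFrame(c(2.9, 0, 0)))  # collinear, d(D,A) = 2.9
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$receptor_resno, 1L)
  expect_equal(hb$angle, 180)
  expect_equal(nrow(detectHbonds(hbFrame(c(4.0, 0, 0)))), 0L)  # d > 3.5
  # d(D,A) = 3.0 but the angle at H is exactly 120 degrees < 135
  a120 <- c(1 + 2.372281 * 0.5, 2.372281 * sqrt(3) / 2, 0)
  expect_equal(sqrt(sum(a120^2)), 3, tolerance = 1e-6)
  expect_equal(nrow(detectHbonds(hbFrame(a120))), 0L)
  # loosening the angle gate admits it
  loose <- contactCriteria(hbAngleMin = 110)
  expect_equal(nrow(detectHbonds(hbFrame(a120), criteria = loose)), 1L)
})

test_that("a hydrogen-free frame yields an empty result with a warning", {
  atoms <- data.frame(name = c("N", "O1"), resname = c("ALA", "LIG"),
                      resno = c(1L, 999L), chain = c("A", "X"),
                      element = c("N", "O"), stringsAsFactors = FALSE)
  traj <- contactTrajectory(atoms, rbind(c(0, 0, 0), c(2.9, 0, 0)),
                            c(FALSE, TRUE))
  expect_warning(hb <- detectHbonds(traj), "no hydrogens")
  expect_equal(nrow(hb), 0L)
})

scFrame <- function(dist, elements = c("C", "C")) {
  atoms <- data.frame(name = c("CB", "C9"), resname = c("ALA", "LIG"),
                      resno = c(7L, 999L), chain = c("A", "X"),
                      element = elements, stringsAsFactors = FALSE)
  contactTrajectory(atoms, rbind(c(0, 0, 0), c(dist, 0, 0)),
                    c(FALSE, TRUE))
}

test_that("side-chain contacts are heavy-atom pairs within the cutoff", {
  expect_equal(detectScContacts(scFrame(4.4)), 7L)
  expect_equal(length(detectScContacts(scFrame(4.6))), 0L)
  # hydrogens never count, however close
  expect_equal(length(detectScContacts(scFrame(1.0, c("H", "H")))), 0L)
  # tightening the cutoff shrinks the contact set
  tight <- contactCriteria(scMax = 4.0)
  expect_equal(length(detectScContacts(scFrame(4.4), criteria = tight)), 0L)
})

test_that("planted contact fractions are recovered exactly from PDB", {
  plan <- data.frame(residue_id = c(3L, 8L, 15L),
                     hb_fraction = c(1, 0.3, 0),
                     sc_fraction = c(1, 0.6, 0))
  gen <- makeBindingTrajectory(plan, nFrames = 100L, seed = 2L)
  traj <- readTrajectoryPDB(gen$path, ligandResname = gen$ligandResname)
  expect_equal(nFrames(traj), 100L)
  prof <- contactProbability(traj)
  expect_equal(prof$residue_id, c(3L, 8L, 15L))
  expect_equal(prof$hb_probability, c(1, 0.3, 0))
  expect_equal(prof$sc_probability, c(1, 0.6, 0))
  expect_equal(prof$n_frames, rep(100L, 3))
})

test_that("contact profiles are invariant under global isometries", {
  plan <- data.frame(residue_id = 1:2, hb_fraction = c(0.5, 0),
                     sc_fraction = c(0.7, 0.2))
  gen <- makeBindingTrajectory(plan, nFrames = 20L, seed = 6L)
  traj <- readTrajectoryPDB(gen$path, ligandResname = "LIG")
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- traj
  for (f in seq_len(nFrames(traj))) {
    moved@coords[, , f] <- traj@coords[, , f] %*% R +
      matrix(c(11, -4, 7), nrow(traj@atoms), 3, byrow = TRUE)
  }
  expect_equal(contactProbability(moved), contactProbability(traj))
})

test_that("fitted RMSD removes rigid-body motion and bounds the raw RMSD", {
  set.seed(12)
  P <- matrix(rnorm(15), ncol = 3)
  expect_equal(rmsdFit(P, P), 0)
  expect_equal(rmsdFit(P + matrix(c(5, 0, 0), 5, 3, byrow = TRUE), P), 0,
               tolerance = 1e-10)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  Q <- P %*% R + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  expect_equal(rmsdFit(Q, P), 0, tolerance = 1e-10)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3)
    B <- matrix(rnorm(9), 3)
    expect_lte(rmsdFit(A, B, doFit = TRUE), rmsdFit(A, B, doFit = FALSE))
  }
  expect_error(rmsdFit(matrix(0, 2, 3), matrix(0, 3, 3)), "equal size")
})

test_that("per-frame trajectory RMSD is zero only at the reference", {
  plan <- data.frame(residue_id = 1L, hb_fraction = 0.5, sc_fraction = 0.5)
  gen <- makeBindingTrajectory(plan, nFrames = 10L, seed = 4L)
  traj <- readTrajectoryPDB(gen$path, ligandResname = "LIG")
  r <- rmsdTrajectory(traj, reference = 1L)
  expect_equal(length(r), 10L)
  expect_equal(r[1], 0, tolerance = 1e-10)
})

test_that("Kabsch superposition matches a rotation-grid oracle", {
  set.seed(23)
  for (i in 1:3) {
    P <- matrix(rnorm(9), 3)
    Q <- matrix(rnorm(9), 3)
    expect_equal(rmsdFit(P, Q), gridRmsd(P, Q), tolerance = 1e-3)
  }
})
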