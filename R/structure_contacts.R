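# Geometric contact analysis of receptor-ligand frames: hydrogen bonds by
# the distance-plus-angle criterion, heavy-atom side-chain contacts,
# per-residue contact probabilities over a trajectory, and Kabsch-fitted
# RMSD. Trajectories are multi-model PDB files (model order = frame order).

# Covalent radii (angstrom) for bond inference; a generic fallback covers
# elements not listed.
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

.covRadius <- function(element) {
  r <- .COV_RADII[toupper(element)]
  r[is.na(r)] <- 0.75
  unname(r)
}

#' Geometric contact criteria
#'
#' Defaults follow the standard geometric definitions: a hydrogen bond
#' requires the acceptor--hydrogen--donor angle (vertex at the hydrogen) to
#' be at least 135 degrees and the acceptor--donor distance at most 3.5
#' angstrom; a side-chain contact requires a non-hydrogen atom pair within
#' 4.5 angstrom.
#'
#' @param hbAngleMin minimum acceptor-hydrogen-donor angle, degrees.
#' @param hbDaMax maximum donor-acceptor distance, angstrom.
#' @param scMax maximum heavy-atom contact distance, angstrom.
#' @param acceptSulfur also treat sulfur as a hydrogen-bond acceptor.
#' @param sideChainOnly restrict receptor contact atoms to side chains
#'   (excludes backbone names N, CA, C, O, OXT).
#' @return a criteria list used by the detection functions.
#' @export
contactCriteria <- function(hbAngleMin = 135, hbDaMax = 3.5, scMax = 4.5,
                            acceptSulfur = FALSE, sideChainOnly = FALSE) {
  stopifnot(hbAngleMin > 0, hbDaMax > 0, scMax > 0)
  list(hbAngleMin = hbAngleMin, hbDaMax = hbDaMax, scMax = scMax,
       acceptSulfur = acceptSulfur, sideChainOnly = sideChainOnly)
}

#' Read a (multi-model) PDB trajectory
#'
#' Each MODEL block is one frame; a single-model file gives a one-frame
#' trajectory. The ligand is selected by residue name and/or chain; all
#' remaining atoms are the receptor.
#'
#' @param path PDB file path.
#' @param ligandResname residue name selecting the ligand atoms.
#' @param ligandChain chain identifier selecting the ligand atoms.
#' @return A [ContactTrajectory-class].
#' @export
readTrajectoryPDB <- function(path, ligandResname = NULL, ligandChain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(ligandResname) && is.null(ligandChain)) {
    stop("select the ligand via ligandResname and/or ligandChain")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || any(is.na(element) | !nzchar(trimws(element)))) {
    element <- suppressWarnings(bio3d::atom2ele(pdb))
  }
  atoms <- data.frame(name = trimws(at$elety), resname = trimws(at$resid),
                      resno = at$resno, chain = at$chain,
                      element = trimws(element), stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  natoms <- nrow(atoms)
  nframes <- nrow(xyz)
  coords <- array(NA_real_, dim = c(natoms, 3L, nframes))
  for (f in seq_len(nframes)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  mask <- rep(TRUE, natoms)
  if (!is.null(ligandResname)) mask <- mask & atoms$resname == ligandResname
  if (!is.null(ligandChain)) mask <- mask & atoms$chain == ligandChain
  contactTrajectory(atoms, coords, mask)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [ContactTrajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  stopifnot(is(traj, "ContactTrajectory"))
  at <- traj@atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  pad_name <- function(nm) {
    # atom names of up to 3 characters start in column 14
    ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  }
  names4 <- pad_name(at$name)
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[, , f]
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), names4, at$resname, at$chain, at$resno,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Coordinates of one frame as an natoms x 3 matrix.
frameCoords <- function(traj, frame) {
  traj@coords[, , frame]
}

# Donor-hydrogen pairs: each hydrogen is assigned to the nearest N/O/S atom
# within covalent-bond distance (< 1.2 x sum of covalent radii) on the same
# side of the ligand mask. Returns a 2-column index matrix (donor, hydrogen).
.donorHydrogens <- function(atoms, xyz, mask) {
  el <- toupper(atoms$element)
  h_idx <- which(el == "H")
  if (!length(h_idx)) return(matrix(integer(0), ncol = 2L))
  d_idx <- which(el %in% c("N", "O", "S"))
  out <- matrix(integer(0), ncol = 2L)
  if (!length(d_idx)) return(out)
  dm <- crossDist(xyz[d_idx, , drop = FALSE], xyz[h_idx, , drop = FALSE])
  lim <- outer(.covRadius(el[d_idx]), rep(.covRadius("H"), length(h_idx)),
               "+") * 1.2
  for (j in seq_along(h_idx)) {
    same <- mask[d_idx] == mask[h_idx[j]]
    ok <- which(same & dm[, j] < lim[, j])
    if (length(ok)) {
      out <- rbind(out, c(d_idx[ok[which.min(dm[ok, j])]], h_idx[j]))
    }
  }
  out
}

#' Detect receptor-ligand hydrogen bonds in one frame
#'
#' A triple (donor, hydrogen, acceptor) qualifies when the hydrogen is
#' covalently bound to the donor, donor and acceptor lie on opposite sides
#' of the ligand mask, the donor-acceptor distance is at most `hbDaMax`,
#' and the angle at the hydrogen (acceptor-hydrogen-donor) is at least
#' `hbAngleMin`. Donors are N/O/S atoms bearing a hydrogen; acceptors are
#' N/O (plus S with `acceptSulfur`).
#'
#' @param traj a [ContactTrajectory-class].
#' @param frame frame index.
#' @param criteria a [contactCriteria()] list.
#' @return data.frame with one row per hydrogen bond: atom indices
#'   (`donor`, `hydrogen`, `acceptor`), the residue number of the
#'   receptor-side atom (`receptor_resno`), distance and angle. A frame
#'   without hydrogens returns an empty result with a warning.
#' @export
detectHbonds <- function(traj, frame = 1L, criteria = contactCriteria()) {
  stopifnot(is(traj, "ContactTrajectory"))
  atoms <- traj@atoms
  xyz <- frameCoords(traj, frame)
  mask <- traj@ligandMask
  el <- toupper(atoms$element)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), receptor_resno = integer(0),
                      distance = numeric(0), angle = numeric(0))
  if (!any(el == "H")) {
    warning("frame has no hydrogens: no hydrogen bonds detectable")
    return(empty)
  }
  dh <- .donorHydrogens(atoms, xyz, mask)
  if (!nrow(dh)) return(empty)
  acc_el <- c("N", "O", if (isTRUE(criteria$acceptSulfur)) "S")
  acc_idx <- which(el %in% acc_el)
  rows <- empty
  for (k in seq_len(nrow(dh))) {
    d <- dh[k, 1L]; h <- dh[k, 2L]
    acc <- acc_idx[mask[acc_idx] != mask[d] & acc_idx != d]
    if (!length(acc)) next
    dda <- crossDist(xyz[d, , drop = FALSE], xyz[acc, , drop = FALSE])[1L, ]
    cand <- which(dda <= criteria$hbDaMax)
    for (ci in cand) {
      a <- acc[ci]
      v1 <- xyz[a, ] - xyz[h, ]
      v2 <- xyz[d, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= criteria$hbAngleMin) {
        rec <- if (mask[d]) a else d
        rows <- rbind(rows, data.frame(
          donor = d, hydrogen = h, acceptor = a,
          receptor_resno = atoms$resno[rec],
          distance = dda[ci], angle = ang))
      }
    }
  }
  rows
}

#' Detect receptor residues in side-chain contact with the ligand
#'
#' A receptor residue is in contact when at least one of its non-hydrogen
#' atoms lies within `scMax` of any non-hydrogen ligand atom.
#'
#' @inheritParams detectHbonds
#' @return sorted integer vector of receptor residue numbers in contact.
#' @export
detectScContacts <- function(traj, frame = 1L, criteria = contactCriteria()) {
  stopifnot(is(traj, "ContactTrajectory"))
  atoms <- traj@atoms
  xyz <- frameCoords(traj, frame)
  mask <- traj@ligandMask
  heavy <- toupper(atoms$element) != "H"
  rec <- which(heavy & !mask)
  if (isTRUE(criteria$sideChainOnly)) {
    rec <- rec[!atoms$name[rec] %in% c("N", "CA", "C", "O", "OXT")]
  }
  lig <- which(heavy & mask)
  if (!length(rec) || !length(lig)) return(integer(0))
  dm <- crossDist(xyz[rec, , drop = FALSE], xyz[lig, , drop = FALSE])
  touching <- apply(dm, 1L, min) <= criteria$scMax
  sort(unique(atoms$resno[rec][touching]))
}

#' Per-residue contact probabilities over a trajectory
#'
#' For every receptor residue, the fraction of frames in which it forms at
#' least one qualifying hydrogen bond (resp. side-chain contact) with the
#' ligand -- the fraction of simulation time the contact is present.
#'
#' @param traj a [ContactTrajectory-class].
#' @param criteria a [contactCriteria()] list.
#' @return data.frame with columns `residue_id`, `residue_name`,
#'   `hb_probability`, `sc_probability`, `n_frames`, one row per receptor
#'   residue in residue-number order.
#' @export
contactProbability <- function(traj, criteria = contactCriteria()) {
  stopifnot(is(traj, "ContactTrajectory"))
  atoms <- traj@atoms
  rec <- !traj@ligandMask
  res_ids <- sort(unique(atoms$resno[rec]))
  res_names <- atoms$resname[rec][match(res_ids, atoms$resno[rec])]
  nf <- nFrames(traj)
  hb_count <- setNames(integer(length(res_ids)), res_ids)
  sc_count <- setNames(integer(length(res_ids)), res_ids)
  has_h <- any(toupper(atoms$element) == "H")
  if (!has_h) {
    warning("trajectory has no hydrogens: hydrogen-bond probabilities are 0")
  }
  for (f in seq_len(nf)) {
    if (has_h) {
      hb <- detectHbonds(traj, f, criteria)
      for (r in unique(hb$receptor_resno)) {
        hb_count[as.character(r)] <- hb_count[as.character(r)] + 1L
      }
    }
    sc <- detectScContacts(traj, f, criteria)
    for (r in sc) sc_count[as.character(r)] <- sc_count[as.character(r)] + 1L
  }
  data.frame(residue_id = res_ids, residue_name = res_names,
             hb_probability = unname(hb_count) / nf,
             sc_probability = unname(sc_count) / nf,
             n_frames = nf, stringsAsFactors = FALSE)
}

# Kabsch optimal rotation aligning the rows of P (mobile) onto Q (reference),
# both already centred. Returns the 3x3 rotation matrix R such that P %*% R
# best matches Q in least squares (proper rotation; reflections excluded).
.kabschRotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' RMSD between two coordinate sets with optional superposition
#'
#' With `doFit = TRUE`, the mobile coordinates are optimally superposed
#' onto the reference by least-squares rigid-body fitting (Kabsch) over
#' `fitSelection`, then the RMSD is measured over `measureSelection`.
#' Without fitting, the raw RMSD over `measureSelection` is returned.
#'
#' @param coords,reference numeric `n x 3` matrices with matching rows.
#' @param fitSelection,measureSelection integer (or logical) atom index
#'   vectors; default all atoms.
#' @param doFit superpose before measuring.
#' @return RMSD in angstrom.
#' @export
rmsdFit <- function(coords, reference, fitSelection = NULL,
                    measureSelection = NULL, doFit = TRUE) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  if (!identical(dim(coords), dim(reference)) || ncol(coords) != 3L) {
    stop("coords and reference must be n x 3 matrices of equal size")
  }
  n <- nrow(coords)
  fitSelection <- if (is.null(fitSelection)) seq_len(n) else {
    seq_len(n)[fitSelection]
  }
  measureSelection <- if (is.null(measureSelection)) seq_len(n) else {
    seq_len(n)[measureSelection]
  }
  if (!length(fitSelection) || !length(measureSelection)) {
    stop("selections must be nonempty")
  }
  if (doFit) {
    cm <- colMeans(coords[fitSelection, , drop = FALSE])
    cr <- colMeans(reference[fitSelection, , drop = FALSE])
    R <- .kabschRotation(
      sweep(coords[fitSelection, , drop = FALSE], 2L, cm),
      sweep(reference[fitSelection, , drop = FALSE], 2L, cr))
    coords <- sweep(sweep(coords, 2L, cm) %*% R, 2L, cr, "+")
  }
  diff <- coords[measureSelection, , drop = FALSE] -
    reference[measureSelection, , drop = FALSE]
  sqrt(mean(rowSums(diff^2)))
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' @param traj a [ContactTrajectory-class].
#' @param reference reference frame index (default the first frame).
#' @param fitSelection,measureSelection,doFit passed to [rmsdFit()].
#' @return numeric vector of per-frame RMSD values (angstrom).
#' @export
rmsdTrajectory <- function(traj, reference = 1L, fitSelection = NULL,
                           measureSelection = NULL, doFit = TRUE) {
  stopifnot(is(traj, "ContactTrajectory"))
  ref <- frameCoords(traj, reference)
  vapply(seq_len(nFrames(traj)), function(f) {
    rmsdFit(frameCoords(traj, f), ref, fitSelection, measureSelection, doFit)
  }, numeric(1))
}
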