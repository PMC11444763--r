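#' Compound library with descriptors and fingerprints
#'
#' An ordered collection of compound records. The `compounds` slot is a
#' data.frame with one row per compound and the canonical columns
#' `id`, `smiles`, `activity_value`, `activity_unit`, `activity_kind`,
#' `dg_exp`, `dg_pred` and `source_round`. Descriptor features and binary
#' fingerprints live in parallel matrices whose rownames are the compound
#' ids; either may have zero columns when not yet attached.
#'
#' Invariants enforced by the validity method: ids are unique and non-missing,
#' the three tables agree row-for-row, fingerprints are logical, and any
#' activity value present is strictly positive.
#'
#' @slot compounds data.frame of per-compound scalar fields.
#' @slot features numeric matrix, one row per compound (descriptor vector).
#' @slot fingerprints logical matrix, one row per compound (bitset).
#' @export
setClass("CompoundLibrary",
  representation(compounds = "data.frame",
                 features = "matrix",
                 fingerprints = "matrix"))

.COMPOUND_COLS <- c("id", "smiles", "activity_value", "activity_unit",
                    "activity_kind", "dg_exp", "dg_pred", "source_round")

setValidity("CompoundLibrary", function(object) {
  cmp <- object@compounds
  msgs <- character(0)
  missing_cols <- setdiff(.COMPOUND_COLS, names(cmp))
  if (length(missing_cols)) {
    return(paste("compounds table lacks columns:",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(cmp$id)) msgs <- c(msgs, "compound ids must not be NA")
  dup <- unique(cmp$id[duplicated(cmp$id)])
  if (length(dup)) {
    msgs <- c(msgs, paste("duplicate compound id(s):",
                          paste(dup, collapse = ", ")))
  }
  n <- nrow(cmp)
  if (nrow(object@features) != n) {
    msgs <- c(msgs, "features must have one row per compound")
  }
  if (nrow(object@fingerprints) != n) {
    msgs <- c(msgs, "fingerprints must have one row per compound")
  }
  if (ncol(object@fingerprints) > 0 && !is.logical(object@fingerprints)) {
    msgs <- c(msgs, "fingerprints must be a logical matrix")
  }
  act <- cmp$activity_value
  if (any(!is.na(act) & act <= 0)) {
    msgs <- c(msgs, "activity_value must be > 0 when present")
  }
  bad_unit <- !is.na(cmp$activity_unit) &
    !cmp$activity_unit %in% c("nM", "uM", "M")
  if (any(bad_unit)) msgs <- c(msgs, "activity_unit must be one of nM/uM/M")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a CompoundLibrary
#'
#' Missing canonical columns in `compounds` are filled with `NA`
#' (`source_round` with 0). Feature/fingerprint matrices default to zero
#' columns and acquire the ids as rownames.
#'
#' @param compounds data.frame with at least an `id` column.
#' @param features optional numeric matrix (one row per compound).
#' @param fingerprints optional logical matrix (one row per compound).
#' @return A [CompoundLibrary-class] object.
#' @examples
#' lib <- CompoundLibrary(data.frame(id = c("a", "b")),
#'                        fingerprints = rbind(c(TRUE, FALSE), c(TRUE, TRUE)))
#' length(lib)
#' @export
CompoundLibrary <- function(compounds, features = NULL, fingerprints = NULL) {
  stopifnot(is.data.frame(compounds))
  if (!"id" %in% names(compounds)) {
    stop("compound table lacks the required 'id' column")
  }
  compounds$id <- as.character(compounds$id)
  n <- nrow(compounds)
  defaults <- list(smiles = NA_character_, activity_value = NA_real_,
                   activity_unit = NA_character_, activity_kind = NA_character_,
                   dg_exp = NA_real_, dg_pred = NA_real_, source_round = 0L)
  for (col in names(defaults)) {
    if (!col %in% names(compounds)) compounds[[col]] <- defaults[[col]]
  }
  compounds <- compounds[, .COMPOUND_COLS, drop = FALSE]
  rownames(compounds) <- NULL
  if (is.null(features)) features <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.null(fingerprints)) {
    fingerprints <- matrix(logical(0), nrow = n, ncol = 0)
  }
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  fingerprints <- as.matrix(fingerprints)
  if (ncol(fingerprints)) storage.mode(fingerprints) <- "logical"
  if (is.null(colnames(features)) && ncol(features)) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  rownames(features) <- compounds$id
  rownames(fingerprints) <- compounds$id
  new("CompoundLibrary", compounds = compounds, features = features,
      fingerprints = fingerprints)
}

#' Interaction-energy time series for one simulation state
#'
#' Van der Waals and Coulomb ligand--surrounding interaction energies over
#' simulation time, for one state (`"bound"` in the receptor complex or
#' `"unbound"` free in solvent) and one replica. Energies are stored in
#' kcal/mol regardless of the units they were read in.
#'
#' @slot times numeric, strictly increasing frame times (ps).
#' @slot vdw numeric, van der Waals interaction energy per frame (kcal/mol).
#' @slot cou numeric, Coulomb interaction energy per frame (kcal/mol).
#' @slot state `"bound"` or `"unbound"`.
#' @slot replica positive integer replica index.
#' @slot sourceUnits units of the file the trace was read from.
#' @export
setClass("EnergyTrace",
  representation(times = "numeric", vdw = "numeric", cou = "numeric",
                 state = "character", replica = "integer",
                 sourceUnits = "character"))

setValidity("EnergyTrace", function(object) {
  n <- length(object@times)
  if (n < 2L) return("an energy trace needs at least 2 frames")
  if (length(object@vdw) != n || length(object@cou) != n) {
    return("times, vdw and cou must have equal length")
  }
  if (any(diff(object@times) <= 0)) {
    return("frame times must be strictly increasing")
  }
  if (!object@state %in% c("bound", "unbound")) {
    return("state must be 'bound' or 'unbound'")
  }
  if (object@replica < 1L) return("replica must be >= 1")
  TRUE
})

#' Construct an EnergyTrace
#'
#' @param times,vdw,cou equal-length numeric vectors; energies in kcal/mol.
#' @param state `"bound"` or `"unbound"`.
#' @param replica positive integer replica index.
#' @param sourceUnits units the data were read in (already converted).
#' @return An [EnergyTrace-class] object.
#' @export
energyTrace <- function(times, vdw, cou, state, replica = 1L,
                        sourceUnits = "kcal/mol") {
  new("EnergyTrace", times = as.numeric(times), vdw = as.numeric(vdw),
      cou = as.numeric(cou), state = state, replica = as.integer(replica),
      sourceUnits = sourceUnits)
}

#' Empirical LIE parameters
#'
#' The linear interaction energy estimator
#' \deqn{\Delta G = \alpha\,\Delta\langle V^{vdw}\rangle +
#'       \beta\,\Delta\langle V^{cou}\rangle + \gamma}
#' uses empirical weights for the van der Waals and Coulomb terms plus a
#' constant offset (kcal/mol). Defaults are the values transferred from a
#' protease system with a similarly shallow binding cleft:
#' alpha = 0.288, beta = -0.049, gamma = -5.88.
#'
#' @slot alpha,beta dimensionless weights.
#' @slot gamma constant offset, kcal/mol.
#' @export
setClass("LIEParameters",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("LIEParameters", function(object) {
  v <- c(object@alpha, object@beta, object@gamma)
  if (length(v) != 3L || any(!is.finite(v))) {
    return("alpha, beta and gamma must be finite scalars")
  }
  TRUE
})

#' @rdname LIEParameters-class
#' @param alpha,beta dimensionless weights of the vdW and Coulomb terms.
#' @param gamma constant offset (kcal/mol).
#' @return A [LIEParameters-class] object.
#' @examples
#' lieParameters()
#' @export
lieParameters <- function(alpha = 0.288, beta = -0.049, gamma = -5.88) {
  new("LIEParameters", alpha = alpha, beta = beta, gamma = gamma)
}

#' Replica-aggregated LIE estimate
#'
#' @slot dg mean binding free energy over replicas (kcal/mol).
#' @slot sem standard error of the mean over replicas (0 when n = 1;
#'   `NA` in pooled mode where no replica spread is defined).
#' @slot nReplicas number of replicas aggregated.
#' @slot perReplica per-replica estimates (empty in pooled mode).
#' @slot pooled whether frames were pooled across replicas instead of
#'   averaging per-replica estimates.
#' @export
setClass("LieEstimate",
  representation(dg = "numeric", sem = "numeric", nReplicas = "integer",
                 perReplica = "numeric", pooled = "logical"))

setValidity("LieEstimate", function(object) {
  if (object@nReplicas < 1L) return("nReplicas must be >= 1")
  if (object@pooled) return(TRUE)
  if (length(object@perReplica) != object@nReplicas) {
    return("perReplica must have nReplicas entries")
  }
  if (abs(object@dg - mean(object@perReplica)) > 1e-9) {
    return("dg must equal mean(perReplica)")
  }
  expected_sem <- if (object@nReplicas == 1L) 0 else {
    sd(object@perReplica) / sqrt(object@nReplicas)
  }
  if (abs(object@sem - expected_sem) > 1e-9) {
    return("sem must be sample-sd(perReplica)/sqrt(n) (0 when n = 1)")
  }
  TRUE
})

#' Fitted affinity regression model
#'
#' Wraps a fitted regression of experimental binding free energy on
#' descriptor features, together with the information needed to apply it to
#' new libraries and the held-out evaluation computed at training time.
#'
#' @slot fit the underlying fitted object (lm, ranger or xgb.Booster).
#' @slot family one of `"linear"`, `"rf"`, `"gbm"`.
#' @slot featureNames descriptor column names seen at training.
#' @slot trainIds ids of the compounds used for training.
#' @slot metrics held-out [evaluateMetrics()] report.
#' @export
setClass("AffinityModel",
  representation(fit = "ANY", family = "character",
                 featureNames = "character", trainIds = "character",
                 metrics = "list"))

#' Receptor-ligand trajectory for contact analysis
#'
#' Per-atom labels plus an `natoms x 3 x nframes` coordinate array (angstrom)
#' and a ligand mask separating the ligand from the receptor.
#'
#' @slot atoms data.frame with columns `name`, `resname`, `resno`, `chain`,
#'   `element`.
#' @slot coords numeric array, dim `c(natoms, 3, nframes)`.
#' @slot ligandMask logical per atom; `TRUE` selects the ligand.
#' @export
setClass("ContactTrajectory",
  representation(atoms = "data.frame", coords = "array",
                 ligandMask = "logical"))

setValidity("ContactTrajectory", function(object) {
  n <- nrow(object@atoms)
  d <- dim(object@coords)
  if (length(d) != 3L || d[1] != n || d[2] != 3L) {
    return("coords must be an natoms x 3 x nframes array")
  }
  if (d[3] < 1L) return("at least one frame required")
  if (length(object@ligandMask) != n) {
    return("ligandMask must have one entry per atom")
  }
  if (!any(object@ligandMask) || all(object@ligandMask)) {
    return("ligandMask must select at least one atom and not all atoms")
  }
  need <- c("name", "resname", "resno", "chain", "element")
  if (!all(need %in% names(object@atoms))) {
    return(paste("atoms table needs columns:", paste(need, collapse = ", ")))
  }
  TRUE
})

#' Construct a ContactTrajectory
#'
#' @param atoms data.frame with columns `name`, `resname`, `resno`, `chain`,
#'   `element`.
#' @param coords numeric array `c(natoms, 3, nframes)`, or an `natoms x 3`
#'   matrix for a single frame.
#' @param ligandMask logical per atom.
#' @return A [ContactTrajectory-class] object.
#' @export
contactTrajectory <- function(atoms, coords, ligandMask) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  new("ContactTrajectory", atoms = atoms, coords = coords,
      ligandMask = as.logical(ligandMask))
}

#' Experimental validation report
#'
#' Pairs LIE-computed binding free energies with experimental values derived
#' from IC50 measurements, with the comparison statistics.
#'
#' @slot entries data.frame, one row per receptor-ligand complex.
#' @slot metrics [evaluateMetrics()] report (empty list when < 3 entries).
#' @slot temperature temperature (K) used for the IC50 conversion.
#' @export
setClass("ValidationReport",
  representation(entries = "data.frame", metrics = "list",
                 temperature = "numeric"))
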