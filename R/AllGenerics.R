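# Generics and basic methods for the core classes.

#' @describeIn CompoundLibrary-class number of compounds.
#' @param x a CompoundLibrary.
#' @export
setMethod("length", "CompoundLibrary", function(x) nrow(x@compounds))

#' Compound ids
#' @param x a [CompoundLibrary-class].
#' @return character vector of ids in record order.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "CompoundLibrary", function(x) x@compounds$id)

#' Compound table accessor
#' @param x a [CompoundLibrary-class].
#' @return the per-compound data.frame.
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname compounds
#' @export
setMethod("compounds", "CompoundLibrary", function(x) x@compounds)

#' Descriptor feature matrix accessor
#' @param x a [CompoundLibrary-class].
#' @return numeric matrix of descriptors (rows = compounds).
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname features
#' @export
setMethod("features", "CompoundLibrary", function(x) x@features)

#' Fingerprint matrix accessor
#' @param x a [CompoundLibrary-class].
#' @return logical matrix of fingerprints (rows = compounds).
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))

#' @rdname fingerprints
#' @export
setMethod("fingerprints", "CompoundLibrary", function(x) x@fingerprints)

#' Fingerprint length in bits
#' @param x a [CompoundLibrary-class].
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname fpBits
#' @export
setMethod("fpBits", "CompoundLibrary", function(x) ncol(x@fingerprints))

#' Descriptor dimension
#' @param x a [CompoundLibrary-class].
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname featureDim
#' @export
setMethod("featureDim", "CompoundLibrary", function(x) ncol(x@features))

#' Predicted binding free energy accessor
#' @param x a [CompoundLibrary-class].
#' @return numeric vector (kcal/mol), `NA` where no prediction was made.
#' @export
setGeneric("dgPred", function(x) standardGeneric("dgPred"))

#' @rdname dgPred
#' @export
setMethod("dgPred", "CompoundLibrary", function(x) {
  setNames(x@compounds$dg_pred, x@compounds$id)
})

#' @rdname dgPred
#' @param value numeric replacement vector.
#' @export
setGeneric("dgPred<-", function(x, value) standardGeneric("dgPred<-"))

#' @rdname dgPred
#' @export
setMethod("dgPred<-", "CompoundLibrary", function(x, value) {
  stopifnot(length(value) == length(x))
  x@compounds$dg_pred <- as.numeric(value)
  validObject(x)
  x
})

#' Experimental binding free energy accessor
#' @param x a [CompoundLibrary-class].
#' @return numeric vector (kcal/mol), `NA` where unknown.
#' @export
setGeneric("dgExp", function(x) standardGeneric("dgExp"))

#' @rdname dgExp
#' @export
setMethod("dgExp", "CompoundLibrary", function(x) {
  setNames(x@compounds$dg_exp, x@compounds$id)
})

#' @describeIn CompoundLibrary-class subset by integer/logical index or by
#'   compound id.
#' @param i index vector (integer, logical, or character ids).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CompoundLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@compounds$id)
    if (anyNA(idx)) {
      stop("unknown compound id(s): ",
           paste(i[is.na(idx)], collapse = ", "))
    }
    i <- idx
  }
  new("CompoundLibrary",
      compounds = x@compounds[i, , drop = FALSE],
      features = x@features[i, , drop = FALSE],
      fingerprints = x@fingerprints[i, , drop = FALSE])
})

setMethod("show", "CompoundLibrary", function(object) {
  cat("CompoundLibrary with", length(object), "compounds\n")
  cat("  features:", featureDim(object), "descriptors;",
      "fingerprints:", fpBits(object), "bits\n")
  n_act <- sum(!is.na(object@compounds$activity_value))
  n_exp <- sum(!is.na(object@compounds$dg_exp))
  n_pred <- sum(!is.na(object@compounds$dg_pred))
  cat("  activity:", n_act, " dg_exp:", n_exp, " dg_pred:", n_pred, "\n")
  invisible(NULL)
})

setMethod("show", "EnergyTrace", function(object) {
  cat(sprintf("EnergyTrace (%s, replica %d): %d frames, t = %g..%g ps\n",
              object@state, object@replica, length(object@times),
              object@times[1], object@times[length(object@times)]))
  cat(sprintf("  <vdw> = %.3f  <cou> = %.3f kcal/mol (full trace)\n",
              mean(object@vdw), mean(object@cou)))
  invisible(NULL)
})

setMethod("show", "LIEParameters", function(object) {
  cat(sprintf("LIE parameters: alpha = %g, beta = %g, gamma = %g kcal/mol\n",
              object@alpha, object@beta, object@gamma))
  invisible(NULL)
})

setMethod("show", "LieEstimate", function(object) {
  if (object@pooled) {
    cat(sprintf("LIE estimate (pooled over %d replicas): %.2f kcal/mol\n",
                object@nReplicas, object@dg))
  } else if (object@nReplicas == 1L) {
    cat(sprintf("LIE estimate: %.2f kcal/mol (single replica, n = 1: no SEM)\n",
                object@dg))
  } else {
    cat(sprintf("LIE estimate: %.2f +/- %.2f kcal/mol (SEM over %d replicas)\n",
                object@dg, object@sem, object@nReplicas))
  }
  invisible(NULL)
})

setMethod("show", "AffinityModel", function(object) {
  cat(sprintf("AffinityModel (%s): %d features, %d training compounds\n",
              object@family, length(object@featureNames),
              length(object@trainIds)))
  m <- object@metrics
  if (length(m)) {
    cat(sprintf("  held-out: RMSE %.3f +/- %.3f, Pearson %.3f, Spearman %.3f (n = %d)\n",
                m$rmse, m$rmse_sd, m$pearson_r, m$spearman_rho, m$n))
  }
  invisible(NULL)
})

#' @describeIn ContactTrajectory-class number of frames.
#' @param x a ContactTrajectory.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "ContactTrajectory", function(x) dim(x@coords)[3])

setMethod("show", "ContactTrajectory", function(object) {
  cat(sprintf("ContactTrajectory: %d atoms (%d ligand), %d frames\n",
              nrow(object@atoms), sum(object@ligandMask), nFrames(object)))
  invisible(NULL)
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d complexes (IC50 -> dG at T = %g K)\n",
              nrow(object@entries), object@temperature))
  if (length(object@metrics)) {
    cat(sprintf("  Pearson R = %.2f, RMSE = %.2f kcal/mol (n = %d)\n",
                object@metrics$pearson_r, object@metrics$rmse,
                object@metrics$n))
  }
  invisible(NULL)
})
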