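# Compound tables, fingerprints and Tanimoto neighbour search. This module
# is the local stand-in for a 2-D similarity query against a large public
# library: similarity is Tanimoto over fixed-length bitsets, and the
# fingerprint source is pluggable (a real chemistry backend can supply the
# bits via the sidecar file; the synthetic generator builds them directly).

#' Read a compound table from CSV
#'
#' One compound per row. The required column is `id`; `smiles`,
#' `activity_value`, `activity_unit` (nM/uM/M), `activity_kind` (Ki/IC50)
#' and `dg_exp` are optional. Rows whose activity fields cannot be parsed
#' (non-numeric or non-positive value, unknown unit or kind) keep their row
#' but have the activity dropped; row order is preserved.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect named list mapping the canonical column roles to the
#'   column names used in the file.
#' @return A [CompoundLibrary-class] with empty feature/fingerprint matrices.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,smiles,activity_value,activity_unit,activity_kind",
#'              "C1,CCO,1000,nM,Ki", "C2,CCN,,,"), f)
#' lib <- readCompoundTable(f)
#' compounds(lib)$activity_value
#' @export
readCompoundTable <- function(path,
                              dialect = list(id = "id", smiles = "smiles",
                                             activity_value = "activity_value",
                                             activity_unit = "activity_unit",
                                             activity_kind = "activity_kind",
                                             dg_exp = "dg_exp")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(dialect$id) || !dialect$id %in% names(raw)) {
    stop("compound table lacks the required 'id' column ('",
         dialect$id %||% "id", "')")
  }
  id <- as.character(raw[[dialect$id]])
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate compound id(s): ", paste(dup, collapse = ", "))
  }
  pick <- function(role) {
    col <- dialect[[role]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  val <- suppressWarnings(as.numeric(pick("activity_value")))
  unit <- as.character(pick("activity_unit"))
  kind <- as.character(pick("activity_kind"))
  n <- length(id)
  if (!length(val)) val <- rep(NA_real_, n)
  if (!length(unit)) unit <- rep(NA_character_, n)
  if (!length(kind)) kind <- rep(NA_character_, n)
  unit[!unit %in% c("nM", "uM", "M")] <- NA_character_
  kind[!kind %in% c("Ki", "IC50")] <- NA_character_
  # an activity is present only when all three fields parsed and value > 0
  ok <- !is.na(val) & val > 0 & !is.na(unit) & !is.na(kind)
  val[!ok] <- NA_real_
  unit[!ok] <- NA_character_
  kind[!ok] <- NA_character_
  smiles <- pick("smiles")
  dg_exp <- pick("dg_exp")
  cmp <- data.frame(id = id,
                    smiles = if (is.null(smiles)) rep(NA_character_, n) else
                      as.character(smiles),
                    activity_value = val, activity_unit = unit,
                    activity_kind = kind,
                    dg_exp = if (is.null(dg_exp)) rep(NA_real_, n) else
                      suppressWarnings(as.numeric(dg_exp)),
                    stringsAsFactors = FALSE)
  CompoundLibrary(cmp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach fingerprints from a sidecar file
#'
#' The sidecar format is one line per compound: `id<TAB>hex`, where the hex
#' string encodes the bitset 4 bits per character, most significant bit
#' first. Every compound in the library must be covered; all fingerprints
#' must have the same bit length.
#'
#' @param library a [CompoundLibrary-class].
#' @param path sidecar file path.
#' @return the library with its `fingerprints` slot filled.
#' @export
readFingerprintSidecar <- function(library, path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("each sidecar line must be 'id<TAB>hex'")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  hex <- vapply(parts, `[[`, character(1), 2L)
  if (length(unique(nchar(hex))) > 1L) {
    stop("all fingerprints must have the same bit length")
  }
  idx <- match(compoundIds(library), ids)
  if (anyNA(idx)) {
    stop("sidecar lacks fingerprints for: ",
         paste(compoundIds(library)[is.na(idx)], collapse = ", "))
  }
  fp <- t(vapply(hex[idx], hexToBits, logical(4L * nchar(hex[1]))))
  rownames(fp) <- compoundIds(library)
  library@fingerprints <- fp
  validObject(library)
  library
}

#' Write a fingerprint sidecar file
#'
#' @param library a [CompoundLibrary-class] with fingerprints attached.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFingerprintSidecar <- function(library, path) {
  fp <- fingerprints(library)
  if (!ncol(fp)) stop("library has no fingerprints")
  hex <- apply(fp, 1L, bitsToHex)
  writeLines(paste(compoundIds(library), hex, sep = "\t"), path)
  invisible(path)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over equal-length bitsets. Two all-zero
#' fingerprints are identical objects, so their similarity is defined as 1.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE, TRUE))  # 0.5
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("fingerprints must have equal bit length (", length(a), " vs ",
         length(b), ")")
  }
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

# All-pairs Tanimoto between the rows of two logical matrices.
# Both-empty pairs get similarity 1, consistent with tanimoto().
tanimotoMatrix <- function(fpA, fpB) {
  if (ncol(fpA) != ncol(fpB)) {
    stop("fingerprints must have equal bit length (", ncol(fpA), " vs ",
         ncol(fpB), ")")
  }
  inter <- tcrossprod(fpA + 0, fpB + 0)
  union <- outer(rowSums(fpA), rowSums(fpB), "+") - inter
  sim <- inter / union
  sim[union == 0] <- 1
  sim
}

#' Similarity neighbour search over a library
#'
#' Returns every library compound whose Tanimoto similarity to at least one
#' seed reaches `simCutoff`. Compounds whose id appears among the seeds are
#' excluded (the search scores newly identified compounds), the result is
#' deduplicated by id and sorted by id, so it does not depend on library
#' record order.
#'
#' @param library a [CompoundLibrary-class] with fingerprints.
#' @param seeds a [CompoundLibrary-class] (possibly a subset of `library`,
#'   possibly external) or a character vector of ids within `library`.
#' @param simCutoff Tanimoto cutoff in `[0, 1]`. The default 0.9 is the
#'   conventional 2-D similarity threshold of public-library searches.
#' @return A [CompoundLibrary-class] subset, sorted by id.
#' @export
neighborSearch <- function(library, seeds, simCutoff = 0.9) {
  if (!is.numeric(simCutoff) || length(simCutoff) != 1L ||
      simCutoff < 0 || simCutoff > 1) {
    stop("simCutoff must be a number in [0, 1]")
  }
  if (is.character(seeds)) seeds <- library[seeds]
  if (!is(seeds, "CompoundLibrary")) {
    stop("seeds must be a CompoundLibrary or a character vector of ids")
  }
  if (length(seeds) == 0L) stop("seed set must not be empty")
  if (fpBits(library) == 0L) stop("library has no fingerprints")
  if (fpBits(seeds) != fpBits(library)) {
    stop("seed fingerprints are incompatible with the library (",
         fpBits(seeds), " vs ", fpBits(library), " bits)")
  }
  candidate <- !compoundIds(library) %in% compoundIds(seeds)
  if (!any(candidate)) return(library[integer(0)])
  sim <- tanimotoMatrix(fingerprints(library)[candidate, , drop = FALSE],
                        fingerprints(seeds))
  hit_ids <- compoundIds(library)[candidate][
    apply(sim, 1L, max) >= simCutoff]
  library[sort(hit_ids)]
}
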