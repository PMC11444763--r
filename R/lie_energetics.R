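# Linear interaction energy (LIE) binding free energy from bound/unbound
# ligand-surrounding interaction-energy traces, with replica aggregation.
# Internal canonical unit is kcal/mol; kJ/mol inputs are converted at I/O
# (1 kcal/mol = 4.184 kJ/mol).

.KJ_PER_KCAL <- 4.184

#' Read an interaction-energy trace in XVG dialect
#'
#' The XVG dialect is the plain-text plotting format of the GROMACS energy
#' tools: lines starting with `#` or `@` are metadata, the rest are
#' whitespace-separated numeric rows of time plus two or more energy
#' columns. The vdW/Coulomb column mapping is taken from `@ sN legend`
#' metadata when legends matching "LJ"/"vdW" and "Coul" are present,
#' otherwise from `columns`.
#'
#' @param path file path.
#' @param state `"bound"` or `"unbound"`.
#' @param replica replica index (>= 1).
#' @param sourceUnits units of the energy columns; kJ/mol values (the
#'   GROMACS default) are divided by 4.184 on read.
#' @param columns optional fallback mapping `c(vdw =, cou =)` giving
#'   1-based energy-column indices (column 1 is the first column after
#'   time).
#' @return An [EnergyTrace-class] in kcal/mol.
#' @export
readXVG <- function(path, state = c("bound", "unbound"), replica = 1L,
                    sourceUnits = c("kJ/mol", "kcal/mol"), columns = NULL) {
  state <- match.arg(state)
  sourceUnits <- match.arg(sourceUnits)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_meta <- grepl("^\\s*[#@]", lines)
  data_lines <- lines[!is_meta]
  if (length(data_lines) < 2L) {
    stop("XVG file has fewer than 2 data rows: ", path)
  }
  fields <- strsplit(trimws(data_lines), "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || ncols < 3L) {
    stop("XVG data rows must all have time plus >= 2 energy columns")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric entries in XVG data rows")
  times <- m[, 1L]
  if (any(diff(times) <= 0)) {
    stop("XVG frame times must be strictly increasing")
  }
  energies <- m[, -1L, drop = FALSE]
  # legend-driven column mapping: '@ s0 legend "LJ (SR)"' etc.
  leg <- regmatches(lines, regexec(
    "^@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"", lines))
  leg <- leg[lengths(leg) == 3L]
  map <- NULL
  if (length(leg)) {
    idx <- as.integer(vapply(leg, `[[`, character(1), 2L)) + 1L
    lab <- vapply(leg, `[[`, character(1), 3L)
    vdw_i <- idx[grepl("LJ|vdw|van der Waals", lab, ignore.case = TRUE)]
    cou_i <- idx[grepl("coul", lab, ignore.case = TRUE)]
    if (length(vdw_i) == 1L && length(cou_i) == 1L) {
      map <- c(vdw = vdw_i, cou = cou_i)
    }
  }
  if (is.null(map)) {
    if (is.null(columns)) {
      stop("cannot determine vdW/Coulomb columns: no usable legends; ",
           "supply columns = c(vdw =, cou =)")
    }
    map <- c(vdw = as.integer(columns[["vdw"]]),
             cou = as.integer(columns[["cou"]]))
  }
  if (any(map < 1L) || any(map > ncol(energies))) {
    stop("column mapping outside the available energy columns")
  }
  scale <- if (sourceUnits == "kJ/mol") 1 / .KJ_PER_KCAL else 1
  energyTrace(times, energies[, map[["vdw"]]] * scale,
              energies[, map[["cou"]]] * scale,
              state = state, replica = replica, sourceUnits = sourceUnits)
}

#' Write an energy trace in XVG dialect
#'
#' Writes kcal/mol values with `@ s0`/`@ s1` legends ("vdW", "Coulomb") so
#' that [readXVG()] with `sourceUnits = "kcal/mol"` round-trips the trace.
#'
#' @param trace an [EnergyTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXVG <- function(trace, path) {
  stopifnot(is(trace, "EnergyTrace"))
  header <- c(
    sprintf("# ligand-surrounding interaction energy (%s, replica %d)",
            trace@state, trace@replica),
    "@    title \"Interaction energy\"",
    "@    xaxis label \"Time (ps)\"",
    "@    yaxis label \"(kcal/mol)\"",
    "@ s0 legend \"vdW\"",
    "@ s1 legend \"Coulomb\"")
  rows <- sprintf("%.6f %.10e %.10e", trace@times, trace@vdw, trace@cou)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Mean interaction energies after equilibration discard
#'
#' Discards the initial `equilFraction` of the simulated time span (frames
#' with time < t_first + equilFraction * (t_last - t_first)) and returns the
#' arithmetic means of the remaining frames.
#'
#' @param trace an [EnergyTrace-class].
#' @param equilFraction fraction of the time span to discard, in `[0, 1)`.
#'   Default 0.2.
#' @return named numeric `c(vdw =, cou =)` in kcal/mol.
#' @export
traceMean <- function(trace, equilFraction = 0.2) {
  stopifnot(is(trace, "EnergyTrace"))
  if (!is.numeric(equilFraction) || equilFraction < 0 || equilFraction >= 1) {
    stop("equilFraction must be in [0, 1)")
  }
  t1 <- trace@times[1L]
  tn <- trace@times[length(trace@times)]
  keep <- trace@times >= t1 + equilFraction * (tn - t1)
  if (!any(keep)) stop("no frames survive the equilibration discard")
  c(vdw = mean(trace@vdw[keep]), cou = mean(trace@cou[keep]))
}

#' LIE binding free energy from mean interaction energies
#'
#' \deqn{\Delta G_{LIE} = \alpha(\langle V^{vdw}\rangle_b -
#'   \langle V^{vdw}\rangle_u) + \beta(\langle V^{cou}\rangle_b -
#'   \langle V^{cou}\rangle_u) + \gamma}
#'
#' @param bound,unbound numeric `c(vdw, cou)` mean interaction energies
#'   (kcal/mol) for the bound and unbound states, as from [traceMean()].
#' @param params a [lieParameters()] object.
#' @return binding free energy, kcal/mol.
#' @examples
#' lieEstimate(c(-10, -5), c(0, 0))  # 0.288*(-10) - 0.049*(-5) - 5.88
#' @export
lieEstimate <- function(bound, unbound, params = lieParameters()) {
  stopifnot(is(params, "LIEParameters"),
            length(bound) == 2L, length(unbound) == 2L)
  bound <- as.numeric(bound); unbound <- as.numeric(unbound)
  if (any(!is.finite(c(bound, unbound)))) {
    stop("mean interaction energies must be finite")
  }
  params@alpha * (bound[1L] - unbound[1L]) +
    params@beta * (bound[2L] - unbound[2L]) + params@gamma
}

#' LIE estimate with replica uncertainty
#'
#' Computes a per-replica LIE estimate from that replica's bound and
#' unbound trace means, then aggregates as mean +/- standard error of the
#' mean over replicas (sample sd with n-1 denominator, divided by sqrt(n);
#' 0 when n = 1). With `pooled = TRUE` the post-equilibration frames of all
#' replicas are pooled per state before a single estimate is computed
#' (no replica spread, so `sem` is `NA`).
#'
#' @param traces list of [EnergyTrace-class] objects covering each replica's
#'   bound and unbound state.
#' @param params a [lieParameters()] object.
#' @param equilFraction equilibration discard passed to [traceMean()].
#' @param sharedUnbound allow a single unbound trace to be shared by every
#'   bound replica (the free-ligand simulation run once).
#' @param pooled pool frames across replicas instead of averaging
#'   per-replica estimates.
#' @return A [LieEstimate-class].
#' @export
lieWithUncertainty <- function(traces, params = lieParameters(),
                               equilFraction = 0.2, sharedUnbound = FALSE,
                               pooled = FALSE) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  if (!all(vapply(traces, is, logical(1), "EnergyTrace"))) {
    stop("traces must be a list of EnergyTrace objects")
  }
  states <- vapply(traces, slot, character(1), "state")
  reps <- vapply(traces, slot, integer(1), "replica")
  key <- paste(states, reps)
  if (anyDuplicated(key)) {
    stop("duplicate trace for state/replica: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  bound <- traces[states == "bound"]
  unbound <- traces[states == "unbound"]
  if (!length(bound) || !length(unbound)) {
    stop("need at least one bound and one unbound trace")
  }
  b_reps <- sort(reps[states == "bound"])
  u_reps <- sort(reps[states == "unbound"])
  shared <- sharedUnbound && length(unbound) == 1L
  if (!shared && !identical(b_reps, u_reps)) {
    stop("mismatched replica sets: bound {",
         paste(b_reps, collapse = ","), "} vs unbound {",
         paste(u_reps, collapse = ","), "}; set sharedUnbound = TRUE to ",
         "reuse a single unbound trace")
  }
  if (pooled) {
    poolMeans <- function(trs) {
      v <- numeric(0); co <- numeric(0)
      for (tr in trs) {
        t1 <- tr@times[1L]; tn <- tr@times[length(tr@times)]
        keep <- tr@times >= t1 + equilFraction * (tn - t1)
        v <- c(v, tr@vdw[keep]); co <- c(co, tr@cou[keep])
      }
      c(vdw = mean(v), cou = mean(co))
    }
    dg <- lieEstimate(poolMeans(bound), poolMeans(unbound), params)
    return(new("LieEstimate", dg = dg, sem = NA_real_,
               nReplicas = length(bound), perReplica = numeric(0),
               pooled = TRUE))
  }
  per <- vapply(seq_along(b_reps), function(i) {
    b <- bound[[which(reps[states == "bound"] == b_reps[i])]]
    u <- if (shared) unbound[[1L]] else {
      unbound[[which(reps[states == "unbound"] == b_reps[i])]]
    }
    lieEstimate(traceMean(b, equilFraction), traceMean(u, equilFraction),
                params)
  }, numeric(1))
  n <- length(per)
  new("LieEstimate", dg = mean(per),
      sem = if (n == 1L) 0 else sd(per) / sqrt(n),
      nReplicas = n, perReplica = per, pooled = FALSE)
}
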