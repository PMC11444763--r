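# Multi-round "similarity search -> predict -> select" screening campaign
# with per-round distribution summaries. Round 0 summarizes predictions on
# the initial library; each later round searches the large library with
# seeds selected from the previous round's output and summarizes only the
# newly found compounds, so each round's distribution stands on its own.

#' Median and quartiles by linear interpolation
#'
#' Quartiles are computed by linear interpolation between order statistics
#' (`stats::quantile` type 7), the common default.
#'
#' @param values numeric vector with at least one value.
#' @return list with `median`, `q1`, `q3`.
#' @examples
#' summarizeDistribution(1:5)  # median 3, q1 2, q3 4
#' @export
summarizeDistribution <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("cannot summarize an empty set of values")
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

# One summary row for a set of predicted compounds.
.roundSummary <- function(hits, roundIndex) {
  dg <- dgPred(hits)
  s <- summarizeDistribution(dg)
  best <- order(dg, compoundIds(hits))[1L]
  data.frame(round_index = as.integer(roundIndex),
             n_unique = length(hits),
             median = s$median, q1 = s$q1, q3 = s$q3,
             best_id = compoundIds(hits)[best],
             best_dg = unname(dg[best]),
             stringsAsFactors = FALSE)
}

#' Run one similarity-search round
#'
#' Finds library compounds similar to the seeds, predicts their binding
#' free energy, and summarizes the predicted distribution over the newly
#' found compounds only (seeds are excluded by [neighborSearch()]).
#'
#' @param library the searchable [CompoundLibrary-class].
#' @param seeds seed compounds ([CompoundLibrary-class] or ids).
#' @param simCutoff Tanimoto cutoff in `[0, 1]`.
#' @param model a fitted [AffinityModel-class].
#' @param roundIndex integer index recorded in the summary.
#' @return list with `hits` (a predicted [CompoundLibrary-class]) and
#'   `summary` (one-row data.frame).
#' @export
runRound <- function(library, seeds, simCutoff, model, roundIndex = NA) {
  hits <- neighborSearch(library, seeds, simCutoff)
  if (length(hits) == 0L) {
    stop("similarity search returned no compounds at cutoff ", simCutoff,
         "; the cutoff may be too high for this library")
  }
  hits <- predictAffinity(model, hits)
  list(hits = hits, summary = .roundSummary(hits, roundIndex))
}

#' Campaign configuration
#'
#' @param nRounds number of similarity-search rounds (>= 1).
#' @param simCutoff Tanimoto cutoff shared by all rounds.
#' @param selection list of length `nRounds`; element r is a
#'   `list(mode =, value =)` selection spec (see [selectTop()]) applied to
#'   the output of round r-1 to obtain the seeds of round r.
#' @param seed campaign seed (recorded; the campaign itself is
#'   deterministic given the model and library).
#' @return a validated config list.
#' @export
campaignConfig <- function(nRounds, simCutoff = 0.9, selection, seed = 1L) {
  nRounds <- as.integer(nRounds)
  if (nRounds < 1L) stop("nRounds must be >= 1")
  if (!is.numeric(simCutoff) || simCutoff < 0 || simCutoff > 1) {
    stop("simCutoff must be in [0, 1]")
  }
  if (!is.list(selection) || length(selection) != nRounds) {
    stop("selection must be a list with one (mode, value) spec per round")
  }
  for (s in selection) {
    if (!all(c("mode", "value") %in% names(s)) ||
        !s$mode %in% c("threshold", "top_k")) {
      stop("each selection spec needs mode ('threshold'/'top_k') and value")
    }
  }
  structure(list(nRounds = nRounds, simCutoff = simCutoff,
                 selection = selection, seed = as.integer(seed)),
            class = "CampaignConfig")
}

#' Run a multi-round enrichment campaign
#'
#' Round 0 predicts binding free energy for every compound of the initial
#' library and summarizes that distribution. For each round r >= 1, seeds
#' are selected from the previous round's output with the r-th selection
#' spec, the large library is searched for similar compounds, and the newly
#' found set is predicted and summarized. Rounds are not merged: each
#' summary describes one search set.
#'
#' @param library the searchable [CompoundLibrary-class] (the stand-in for
#'   a large public library).
#' @param initialLibrary the starting compound set whose predictions seed
#'   round 1.
#' @param config a [campaignConfig()].
#' @param model a fitted [AffinityModel-class].
#' @return list with `summaries` (data.frame, one row per round including
#'   round 0), `hits` (final round's compounds sorted by ascending
#'   `dg_pred`), and `seeds` (list of per-round seed id vectors).
#' @export
runCampaign <- function(library, initialLibrary, config, model) {
  stopifnot(inherits(config, "CampaignConfig"))
  current <- predictAffinity(model, initialLibrary)
  summaries <- .roundSummary(current, 0L)
  seed_ids <- vector("list", config$nRounds)
  for (r in seq_len(config$nRounds)) {
    sel <- config$selection[[r]]
    seeds <- selectTop(current, sel$mode, sel$value)
    if (length(seeds) == 0L) {
      stop("selection after round ", r - 1L,
           " yielded no seed compounds for round ", r)
    }
    seed_ids[[r]] <- compoundIds(seeds)
    rr <- runRound(library, seeds, config$simCutoff, model, roundIndex = r)
    summaries <- rbind(summaries, rr$summary)
    current <- rr$hits
  }
  final <- selectTop(current, "top_k", length(current))  # sort asc, tie by id
  list(summaries = summaries, hits = final, seeds = seed_ids)
}
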