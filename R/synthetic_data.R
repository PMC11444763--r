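# Synthetic generators emulating the statistical structure of the upstream
# inputs, so the whole pipeline runs and is testable at desk scale: a
# scaffold-clustered library with descriptor-linked affinities, stationary
# AR(1) interaction-energy traces, and trajectories with planted per-residue
# contact fractions. Every generator is a pure function of its seed and
# returns the ground truth needed for assertions.

#' Generate a scaffold-clustered compound library
#'
#' Compounds come in scaffold clusters. Each scaffold has a descriptor
#' centre (members jittered around it) and a fingerprint mask of
#' `maskWeight` on-bits; each member's fingerprint adds at most k extra
#' bits to the mask, with k chosen analytically so that every
#' within-scaffold pair has Tanimoto similarity at least
#' `withinScaffoldMinTanimoto`: for a shared mask of m bits and at most k
#' private extra bits per member, similarity is at least m / (m + 2k), so
#' k = floor(m (1 - t) / (2 t)).
#'
#' Experimental binding free energies are linear in the descriptors plus
#' Gaussian noise. An optional potent scaffold has its centre shifted along
#' the coefficient vector so its members' mean free energy equals
#' `potentScaffold$meanDg` -- a planted cluster of strong binders that a
#' trained model can rediscover.
#'
#' Defaults emulate the screened compound sets: about 2000 compounds whose
#' free energies centre near -7.4 kcal/mol with an interquartile range of
#' about 1.3-1.5 kcal/mol (the spread of the screened library's predicted
#' affinities), label noise of 1 kcal/mol, and a 0.9 within-scaffold
#' similarity floor (the conventional 2-D search threshold).
#'
#' @param nScaffolds,nPerScaffold cluster count and size.
#' @param featureDim descriptor dimension.
#' @param fpBits fingerprint length in bits.
#' @param maskWeight on-bits per scaffold mask (default `fpBits / 8`).
#' @param coefficients affinity coefficients (kcal/mol per descriptor
#'   unit); drawn N(0, 0.35) from the seed when `NULL`.
#' @param scaffoldSpread per-dimension standard deviation of the scaffold
#'   descriptor centres. The default 0.9 puts the between-scaffold affinity
#'   spread near 1 kcal/mol, matching the screened library's distribution
#'   width.
#' @param intercept affinity intercept, kcal/mol.
#' @param labelNoiseSd Gaussian label noise sd, kcal/mol.
#' @param withinScaffoldMinTanimoto within-scaffold similarity floor in
#'   (0, 1].
#' @param potentScaffold optional `list(index =, meanDg =)`.
#' @param seed RNG seed; the generator is a pure function of it.
#' @return list with `library` (a [CompoundLibrary-class] with features,
#'   fingerprints and `dg_exp`) and `truth` (coefficients, intercept,
#'   scaffold membership, masks, noise sd, potent scaffold).
#' @export
makeLibrary <- function(nScaffolds = 40L, nPerScaffold = 50L,
                        featureDim = 8L, fpBits = 512L, maskWeight = NULL,
                        coefficients = NULL, scaffoldSpread = 0.9,
                        intercept = -7.4,
                        labelNoiseSd = 1.0,
                        withinScaffoldMinTanimoto = 0.9,
                        potentScaffold = NULL, seed = 1L) {
  stopifnot(nScaffolds >= 1L, nPerScaffold >= 1L, featureDim >= 1L,
            fpBits >= 4L, labelNoiseSd >= 0)
  t <- withinScaffoldMinTanimoto
  if (!is.numeric(t) || t <= 0 || t > 1) {
    stop("withinScaffoldMinTanimoto must be in (0, 1]")
  }
  m <- as.integer(maskWeight %||% max(8L, fpBits %/% 8L))
  if (m > fpBits) {
    stop("fp_bits too small: the scaffold mask needs ", m,
         " bits but only ", fpBits, " are available")
  }
  k <- floor(m * (1 - t) / (2 * t))
  if (nPerScaffold > 1L && k > fpBits - m) {
    # cannot place the allowed private bits outside the mask
    k <- fpBits - m
  }
  withSeed(seed, {
    beta <- coefficients %||% rnorm(featureDim, 0, 0.35)
    if (length(beta) != featureDim) {
      stop("coefficients must have length featureDim")
    }
    centers <- matrix(rnorm(nScaffolds * featureDim, 0, scaffoldSpread),
                      nrow = nScaffolds)
    if (!is.null(potentScaffold)) {
      i <- potentScaffold$index
      stopifnot(i >= 1L, i <= nScaffolds, is.numeric(potentScaffold$meanDg))
      delta <- potentScaffold$meanDg -
        (sum(centers[i, ] * beta) + intercept)
      centers[i, ] <- centers[i, ] + delta * beta / sum(beta^2)
    }
    n <- nScaffolds * nPerScaffold
    scaffold <- rep(seq_len(nScaffolds), each = nPerScaffold)
    X <- centers[scaffold, , drop = FALSE] +
      matrix(rnorm(n * featureDim, 0, 0.5), nrow = n)
    colnames(X) <- paste0("f", seq_len(featureDim))
    dg <- as.numeric(X %*% beta) + intercept + rnorm(n, 0, labelNoiseSd)
    masks <- lapply(seq_len(nScaffolds), function(s) {
      sort(sample.int(fpBits, m))
    })
    fp <- matrix(FALSE, nrow = n, ncol = fpBits)
    for (i in seq_len(n)) {
      on <- masks[[scaffold[i]]]
      if (k > 0L) {
        pool <- setdiff(seq_len(fpBits), on)
        on <- c(on, sample(pool, min(k, length(pool))))
      }
      fp[i, on] <- TRUE
    }
    ids <- sprintf("S%03dC%04d", scaffold,
                   sequence(rep(nPerScaffold, nScaffolds)))
    lib <- CompoundLibrary(
      data.frame(id = ids, dg_exp = dg, source_round = 0L,
                 stringsAsFactors = FALSE),
      features = X, fingerprints = fp)
    list(library = lib,
         truth = list(coefficients = beta, intercept = intercept,
                      scaffold = scaffold, masks = masks,
                      maskWeight = m, extraBits = k,
                      labelNoiseSd = labelNoiseSd,
                      potentScaffold = potentScaffold))
  })
}

# Stationary AR(1) series with given mean, marginal sd and lag-1
# autocorrelation phi; the recursion itself runs in C via stats::filter.
.ar1 <- function(n, mu, sdev, phi) {
  if (sdev == 0) return(rep(mu, n))
  innov <- rnorm(n, 0, sdev * sqrt(1 - phi^2))
  z0 <- rnorm(1, 0, sdev)
  mu + as.numeric(filter(innov, phi, method = "recursive", init = z0))
}

#' Generate autocorrelated bound/unbound energy traces
#'
#' Each series (vdW and Coulomb, bound and unbound, per replica) is a
#' stationary first-order autoregressive process with the requested
#' stationary mean, marginal standard deviation and autocorrelation time
#' (lag-1 autocorrelation `exp(-dt/tau)`). Real interaction-energy series
#' are autocorrelated, so calibration checks against these traces are
#' honest about the effective sample size.
#'
#' Defaults emulate the production setup: 25 000 frames at 2 ps spacing
#' (a 50 ns trajectory), two replicas, fluctuations of 3 kcal/mol with a
#' 5 ps correlation time.
#'
#' @param trueMeans named numeric `c(vdw_b, cou_b, vdw_u, cou_u)`:
#'   stationary means, kcal/mol.
#' @param marginalSd marginal standard deviation, kcal/mol.
#' @param tau autocorrelation time, ps.
#' @param nFrames frames per trace.
#' @param dt frame spacing, ps.
#' @param nReplicas number of replicas (bound/unbound trace pairs).
#' @param params [lieParameters()] used for the analytic ground truth.
#' @param seed RNG seed.
#' @return list with `traces` (list of [EnergyTrace-class]), `analyticDg`
#'   (the LIE estimate at the true means) and `trueMeans`.
#' @export
makeEnergyTraces <- function(trueMeans = c(vdw_b = -40, cou_b = -30,
                                           vdw_u = -25, cou_u = -25),
                             marginalSd = 3, tau = 5, nFrames = 25000L,
                             dt = 2, nReplicas = 2L,
                             params = lieParameters(), seed = 1L) {
  stopifnot(marginalSd >= 0, dt > 0, tau > 0, nFrames >= 2L, nReplicas >= 1L)
  need <- c("vdw_b", "cou_b", "vdw_u", "cou_u")
  if (!all(need %in% names(trueMeans))) {
    stop("trueMeans needs named entries: ", paste(need, collapse = ", "))
  }
  phi <- exp(-dt / tau)
  times <- seq(0, by = dt, length.out = nFrames)
  traces <- withSeed(seed, {
    out <- list()
    for (r in seq_len(nReplicas)) {
      out[[length(out) + 1L]] <- energyTrace(
        times, .ar1(nFrames, trueMeans[["vdw_b"]], marginalSd, phi),
        .ar1(nFrames, trueMeans[["cou_b"]], marginalSd, phi),
        state = "bound", replica = r)
      out[[length(out) + 1L]] <- energyTrace(
        times, .ar1(nFrames, trueMeans[["vdw_u"]], marginalSd, phi),
        .ar1(nFrames, trueMeans[["cou_u"]], marginalSd, phi),
        state = "unbound", replica = r)
    }
    out
  })
  analytic <- lieEstimate(c(trueMeans[["vdw_b"]], trueMeans[["cou_b"]]),
                          c(trueMeans[["vdw_u"]], trueMeans[["cou_u"]]),
                          params)
  list(traces = traces, analyticDg = analytic, trueMeans = trueMeans)
}

#' Generate a trajectory with planted per-residue contact fractions
#'
#' Builds a toy receptor-ligand system and a multi-model PDB trajectory in
#' which each receptor residue forms a hydrogen bond with the ligand in
#' exactly `round(hb_fraction * nFrames)` frames and a side-chain contact
#' in exactly `round(sc_fraction * nFrames)` frames; contact frames are
#' chosen by a seeded shuffle. Planting is exact-count rather than
#' Bernoulli, so probability recovery is an equality test.
#'
#' In-contact geometry: the residue's donor nitrogen sits collinear with
#' its hydrogen at 2.9 angstrom from a ligand oxygen acceptor (angle at
#' the hydrogen 180 degrees); a side-chain-only contact places the
#' residue's carbon 4.0 angstrom from a ligand carbon while keeping the
#' donor far from the acceptor. Out-of-contact frames keep all residue
#' atoms at least 6 angstrom from every ligand atom. Because any
#' qualifying hydrogen bond places two heavy atoms within the side-chain
#' cutoff, hydrogen-bond frames are planted as a subset of side-chain
#' frames and `sc_fraction >= hb_fraction` is required.
#'
#' @param residuePlan data.frame with columns `residue_id`, `hb_fraction`,
#'   `sc_fraction` (fractions in `[0, 1]`).
#' @param nFrames number of frames.
#' @param seed RNG seed for the frame shuffle.
#' @param path output PDB path (default a temp file).
#' @return list with `path` (the written multi-model PDB), `truth`
#'   (data.frame of realized, exact fractions) and `ligandResname`
#'   (`"LIG"`).
#' @export
makeBindingTrajectory <- function(residuePlan, nFrames = 100L, seed = 1L,
                                  path = tempfile(fileext = ".pdb")) {
  stopifnot(is.data.frame(residuePlan),
            all(c("residue_id", "hb_fraction", "sc_fraction") %in%
                  names(residuePlan)),
            nFrames >= 1L)
  hb <- residuePlan$hb_fraction
  sc <- residuePlan$sc_fraction
  if (any(hb < 0 | hb > 1 | sc < 0 | sc > 1)) {
    stop("contact fractions must be in [0, 1]")
  }
  if (any(sc < hb)) {
    stop("sc_fraction must be >= hb_fraction: a geometric hydrogen bond ",
         "necessarily places heavy atoms within the side-chain cutoff")
  }
  nres <- nrow(residuePlan)
  # ligand: acceptor oxygen at the origin, two carbons off to one side
  lig_atoms <- data.frame(
    name = c("O1", "C1", "C2"), resname = "LIG", resno = 9999L,
    chain = "X", element = c("O", "C", "C"), stringsAsFactors = FALSE)
  lig_xyz <- rbind(c(0, 0, 0), c(0, 0, 8), c(0, 0, 9.5))
  res_atoms <- do.call(rbind, lapply(seq_len(nres), function(i) {
    data.frame(name = c("N", "H", "CB"), resname = "ALA",
               resno = as.integer(residuePlan$residue_id[i]), chain = "A",
               element = c("N", "H", "C"), stringsAsFactors = FALSE)
  }))
  atoms <- rbind(res_atoms, lig_atoms)
  natoms <- nrow(atoms)
  theta <- 2 * pi * (seq_len(nres) - 1L) / max(nres, 1L)
  u <- cbind(cos(theta), sin(theta), 0)
  n_hb <- round(hb * nFrames)
  n_sc <- round(sc * nFrames)
  coords <- array(NA_real_, dim = c(natoms, 3L, nFrames))
  assignments <- withSeed(seed, {
    lapply(seq_len(nres), function(i) sample.int(nFrames))
  })
  for (i in seq_len(nres)) {
    ord <- assignments[[i]]
    sc_frames <- ord[seq_len(n_sc[i])]
    hb_frames <- ord[seq_len(n_hb[i])]  # subset of the SC frames
    rows <- (i - 1L) * 3L + 1:3
    for (f in seq_len(nFrames)) {
      if (f %in% hb_frames) {
        # collinear N-H...O at 2.9 angstrom along this residue's direction
        xyz <- rbind(2.9 * u[i, ], 1.9 * u[i, ], 4.4 * u[i, ])
      } else if (f %in% sc_frames) {
        # CB 4.0 angstrom from ligand C1; donor kept far from the acceptor
        base <- c(0, 0, 8)
        xyz <- rbind(base + 7.0 * u[i, ], base + 6.0 * u[i, ],
                     base + 4.0 * u[i, ])
      } else {
        base <- (40 + 5 * i) * u[i, ]
        xyz <- rbind(base, base + c(0, 0, 1), base + c(0, 0, 2.5))
      }
      coords[rows, , f] <- xyz
    }
  }
  lig_rows <- nres * 3L + 1:3
  for (f in seq_len(nFrames)) coords[lig_rows, , f] <- lig_xyz
  traj <- contactTrajectory(atoms, coords,
                            ligandMask = atoms$resname == "LIG")
  writeTrajectoryPDB(traj, path)
  list(path = path,
       truth = data.frame(residue_id = as.integer(residuePlan$residue_id),
                          hb_fraction = n_hb / nFrames,
                          sc_fraction = n_sc / nFrames),
       ligandResname = "LIG")
}

#' Synthetic two-round enrichment benchmark
#'
#' End-to-end exercise of the screening campaign on generated data: build a
#' scaffold-clustered library with one planted potent scaffold (members
#' averaging `potentDg` kcal/mol), train an affinity model on it, and run a
#' two-round campaign (threshold selection, then top-k). The initial
#' screening set mirrors the role of the diverse starting library of a real
#' campaign: every background compound plus the first `nInitialPotent`
#' members of the potent scaffold, so the potent chemotype is represented
#' but most of its members remain to be discovered by similarity search.
#'
#' @param seed generator/campaign seed.
#' @param nScaffolds,nPerScaffold library shape (default 2000 compounds).
#' @param potentDg mean free energy of the potent scaffold, kcal/mol.
#' @param family model family for [trainAffinityModel()]. The default
#'   `"gbm"` mirrors the screening model family; `"linear"` is faster.
#' @param nInitialPotent potent-scaffold members seeded into the initial
#'   screening set.
#' @param threshold round-1 seed selection threshold, kcal/mol.
#' @param topK round-2 seed count.
#' @param simCutoff Tanimoto cutoff.
#' @return list with the campaign `summaries`, `bestId`, `bestInPotent`
#'   (whether the final best hit belongs to the potent scaffold),
#'   `mediansNonIncreasing`, and the campaign `result`.
#' @export
syntheticEnrichmentBenchmark <- function(seed = 1L, nScaffolds = 40L,
                                         nPerScaffold = 50L,
                                         potentDg = -11, family = "gbm",
                                         nInitialPotent = 5L,
                                         threshold = -10,
                                         topK = 9L, simCutoff = 0.9) {
  gen <- makeLibrary(nScaffolds = nScaffolds, nPerScaffold = nPerScaffold,
                     potentScaffold = list(index = 1L, meanDg = potentDg),
                     seed = seed)
  lib <- gen$library
  n <- length(lib)
  model <- trainAffinityModel(lib, family = family,
                              nTrain = round(0.75 * n),
                              splitSeed = seed, modelSeed = seed,
                              nBoot = 50L)
  potent_ids <- compoundIds(lib)[gen$truth$scaffold == 1L]
  background <- setdiff(compoundIds(lib), potent_ids)
  init_ids <- c(head(potent_ids, nInitialPotent), background)
  config <- campaignConfig(
    nRounds = 2L, simCutoff = simCutoff,
    selection = list(list(mode = "threshold", value = threshold),
                     list(mode = "top_k", value = topK)),
    seed = seed)
  result <- runCampaign(lib, lib[init_ids], config, model)
  med <- result$summaries$median
  best <- result$summaries$best_id[nrow(result$summaries)]
  list(summaries = result$summaries, bestId = best,
       bestInPotent = best %in% potent_ids,
       mediansNonIncreasing = all(diff(med) <= 1e-9),
       result = result)
}
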