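# Affinity regression on molecular descriptors, thermodynamic conversion of
# measured activities, model evaluation with bootstrap uncertainties, and
# top-compound selection.

#' Convert an inhibition constant to binding free energy
#'
#' \deqn{\Delta G = R T \ln K_i}
#' with the gas constant R = 1.987e-3 kcal/(mol K). `ki` must be in molar
#' units; sub-molar constants give negative free energies. The default
#' temperature of 300 K is the one under which the packaged experimental
#' validation table's free energies were derived (see the methods vignette
#' for the 298-vs-300 K discussion); pass `temperature = 298` for the
#' conventional standard temperature.
#'
#' @param ki inhibition constant(s), molar. Must be > 0.
#' @param temperature absolute temperature, K.
#' @return binding free energy, kcal/mol (vectorized over `ki`).
#' @examples
#' kiToDG(1e-6, temperature = 300)  # -8.24
#' @export
kiToDG <- function(ki, temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (any(!is.finite(ki)) || any(ki <= 0)) {
    stop("ki must be finite and > 0 (molar)")
  }
  .RGAS * temperature * log(ki)
}

#' Convert an IC50 to binding free energy
#'
#' Identical contract to [kiToDG()]: \eqn{\Delta G = R T \ln(IC_{50})}
#' with the concentration in molar units.
#'
#' @inheritParams kiToDG
#' @param ic50 half-maximal inhibitory concentration(s), molar. Must be > 0.
#' @return binding free energy, kcal/mol.
#' @examples
#' ic50ToDG(100e-9, temperature = 300)  # -9.61
#' @export
ic50ToDG <- function(ic50, temperature = 300) {
  kiToDG(ic50, temperature = temperature)
}

# nM/uM/M -> molar. Conversion factors exact.
activityToMolar <- function(value, unit) {
  factor <- c(nM = 1e-9, uM = 1e-6, M = 1)[unit]
  if (anyNA(factor)) stop("activity unit must be one of nM/uM/M")
  unname(value * factor)
}

#' Evaluate predictions against ground truth
#'
#' Point metrics (RMSE, Pearson R, Spearman rho) on the full vectors, with
#' uncertainties estimated as the standard deviation of each metric over
#' paired nonparametric bootstrap resamples (pred/truth pairs resampled
#' jointly).
#'
#' @param pred,truth equal-length numeric vectors (length >= 3).
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @return list with `rmse`, `rmse_sd`, `pearson_r`, `pearson_sd`,
#'   `spearman_rho`, `spearman_sd`, `n`, `n_boot`, `seed`. When either
#'   vector has zero variance the correlations are `NA` (with a warning);
#'   the RMSE is still returned.
#' @examples
#' evaluateMetrics(c(1, 2, 3), c(1, 2, 3), nBoot = 50, seed = 1)$rmse
#' @export
evaluateMetrics <- function(pred, truth, nBoot = 1000L, seed = 1L) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length")
  }
  n <- length(pred)
  if (n < 3L) stop("need at least 3 pairs to evaluate")
  if (any(!is.finite(pred)) || any(!is.finite(truth))) {
    stop("pred and truth must be finite")
  }
  rmse <- sqrt(mean((pred - truth)^2))
  degenerate <- sd(pred) == 0 || sd(truth) == 0
  if (degenerate) {
    warning("zero variance in pred or truth: correlations undefined")
    pe <- NA_real_; sp <- NA_real_
  } else {
    pe <- cor(pred, truth)
    sp <- cor(pred, truth, method = "spearman")
  }
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      p <- pred[i]; t <- truth[i]
      r <- sqrt(mean((p - t)^2))
      if (sd(p) == 0 || sd(t) == 0) {
        c(r, NA_real_, NA_real_)
      } else {
        c(r, cor(p, t), cor(p, t, method = "spearman"))
      }
    }, numeric(3))
  })
  list(rmse = rmse, rmse_sd = sd(boot[1, ]),
       pearson_r = pe, pearson_sd = sd(boot[2, ], na.rm = TRUE),
       spearman_rho = sp, spearman_sd = sd(boot[3, ], na.rm = TRUE),
       n = n, n_boot = as.integer(nBoot), seed = as.integer(seed))
}

.featureFrame <- function(X) as.data.frame(X)

#' Train an affinity regression model
#'
#' Randomly splits the library into `nTrain` training compounds and a
#' held-out test set (`n - nTrain` compounds), fits the requested family on
#' descriptor features against `dg_exp`, and evaluates on the held-out set.
#' Deterministic given `splitSeed` and `modelSeed`.
#'
#' Families: `"linear"` (ordinary least squares), `"rf"` (random forest via
#' ranger), `"gbm"` (gradient-boosted trees via xgboost, the family used for
#' the screening predictions).
#'
#' @param library a [CompoundLibrary-class] with features and `dg_exp`.
#' @param family model family.
#' @param nTrain number of training compounds (0 < nTrain < n).
#' @param splitSeed seed for the random train/test split.
#' @param modelSeed seed for stochastic model families.
#' @param nBoot bootstrap resamples for the held-out metrics.
#' @param hyper named list of family hyperparameters. For `"gbm"`:
#'   `nrounds` (300), `eta` (0.1), `max_depth` (4); for `"rf"`:
#'   `num.trees` (500).
#' @return An [AffinityModel-class]; held-out metrics in `modelMetrics()`.
#' @export
trainAffinityModel <- function(library,
                               family = c("gbm", "linear", "rf"),
                               nTrain, splitSeed = 1L, modelSeed = 1L,
                               nBoot = 1000L, hyper = list()) {
  family <- match.arg(family)
  n <- length(library)
  if (!is.numeric(nTrain) || nTrain <= 0 || nTrain >= n) {
    stop("nTrain must satisfy 0 < nTrain < ", n)
  }
  if (featureDim(library) == 0L) stop("library has no descriptor features")
  idx_train <- withSeed(splitSeed, sort(sample.int(n, nTrain)))
  idx_test <- setdiff(seq_len(n), idx_train)
  y <- dgExp(library)
  miss_train <- compoundIds(library)[idx_train][is.na(y[idx_train])]
  if (length(miss_train)) {
    stop("training compounds lack dg_exp: ",
         paste(miss_train, collapse = ", "))
  }
  miss_test <- compoundIds(library)[idx_test][is.na(y[idx_test])]
  if (length(miss_test)) {
    stop("held-out compounds lack dg_exp: ",
         paste(miss_test, collapse = ", "))
  }
  X <- features(library)
  Xtr <- X[idx_train, , drop = FALSE]
  ytr <- unname(y[idx_train])
  fit <- switch(family,
    linear = {
      df <- .featureFrame(Xtr); df$.dg <- ytr
      lm(.dg ~ ., data = df)
    },
    rf = {
      nt <- hyper$num.trees %||% 500L
      ranger::ranger(x = .featureFrame(Xtr), y = ytr, num.trees = nt,
                     seed = as.integer(modelSeed), num.threads = 1L)
    },
    gbm = {
      params <- list(objective = "reg:squarederror",
                     eta = hyper$eta %||% 0.1,
                     max_depth = hyper$max_depth %||% 4L,
                     nthread = 1L, seed = as.integer(modelSeed))
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(Xtr, label = ytr),
                         nrounds = hyper$nrounds %||% 300L, verbose = 0)
    })
  model <- new("AffinityModel", fit = fit, family = family,
               featureNames = colnames(X), trainIds =
                 compoundIds(library)[idx_train], metrics = list())
  pred_test <- .predictMatrix(model, X[idx_test, , drop = FALSE])
  model@metrics <- evaluateMetrics(pred_test, unname(y[idx_test]),
                                   nBoot = nBoot, seed = splitSeed)
  model
}

#' Held-out metrics of a fitted model
#' @param model an [AffinityModel-class].
#' @return the [evaluateMetrics()] report computed at training time.
#' @export
modelMetrics <- function(model) {
  stopifnot(is(model, "AffinityModel"))
  model@metrics
}

.predictMatrix <- function(model, X) {
  unname(switch(model@family,
    linear = predict(model@fit, newdata = .featureFrame(X)),
    rf = predict(model@fit, data = .featureFrame(X),
                 num.threads = 1L)$predictions,
    gbm = predict(model@fit, xgboost::xgb.DMatrix(X))))
}

#' Predict binding free energy for every library compound
#'
#' @param model a fitted [AffinityModel-class].
#' @param library a [CompoundLibrary-class] whose feature matrix matches the
#'   training descriptors.
#' @return the library with `dg_pred` filled for every record.
#' @export
predictAffinity <- function(model, library) {
  stopifnot(is(model, "AffinityModel"), is(library, "CompoundLibrary"))
  X <- features(library)
  if (ncol(X) != length(model@featureNames)) {
    stop("feature dimension mismatch: model expects ",
         length(model@featureNames), " descriptors, library has ", ncol(X))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), model@featureNames)) {
    stop("feature names do not match the training descriptors")
  }
  dgPred(library) <- .predictMatrix(model, X)
  library
}

#' Select top-ranked compounds by predicted affinity
#'
#' Threshold mode keeps records with `dg_pred` strictly below `value`
#' ("lower than" read as a strict inequality); top-k mode keeps the `value`
#' records with the smallest `dg_pred`. Both return the subset sorted by
#' ascending `dg_pred` with ties broken by id, so selection is
#' deterministic.
#'
#' @param library a [CompoundLibrary-class] with `dg_pred` filled.
#' @param mode `"threshold"` or `"top_k"`.
#' @param value the threshold (kcal/mol) or k.
#' @return An ordered [CompoundLibrary-class] subset.
#' @export
selectTop <- function(library, mode = c("threshold", "top_k"), value) {
  mode <- match.arg(mode)
  dg <- dgPred(library)
  if (anyNA(dg)) stop("all records need dg_pred before selection")
  ord <- order(dg, compoundIds(library))
  if (mode == "threshold") {
    keep <- ord[dg[ord] < value]
  } else {
    k <- as.integer(value)
    if (k < 0L || k > length(library)) {
      stop("top_k selection needs 0 <= k <= ", length(library))
    }
    keep <- head(ord, k)
  }
  library[keep]
}
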