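# Compound-level cross-validation of the multi-task network.

#' Cross-validated activity scores
#'
#' Compound-level k-fold cross-validation: for each fold, a network is
#' initialized and trained on the remaining compounds (with a seeded 20%
#' monitoring split of the training compounds driving early stopping) and
#' scores the held-out compounds. Every compound's scores therefore come
#' from a model that never saw it. The per-feature normalizer is refit
#' inside each training fold, so no held-out statistics leak in.
#'
#' @param X raw (unnormalized) feature matrix, compounds x features.
#' @param Y 0/1 label matrix aligned with `X`.
#' @param k number of folds; @param seed master seed (folds, monitor
#'   splits, weight init and shuffles all derive from it);
#' @param config a [trainingConfig()]; its `shuffleSeed` is re-derived per
#'   fold; @param nHidden hidden layer width;
#' @param monitorFrac fraction of training compounds held out for early
#'   stopping.
#' @return list: `scores` (matrix, held-out scores for every compound),
#'   `folds` (assignment), `models` (per-fold trained [AnnModel-class]),
#'   `pooledCounts` helper via [cvPooledMetrics()].
#' @export
cvProfile <- function(X, Y, k = 5, seed = 1, config = trainingConfig(),
                      nHidden = 32, monitorFrac = 0.2) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  folds <- splitFolds(nrow(X), k, seed)
  P <- matrix(NA_real_, nrow(X), ncol(Y), dimnames = dimnames(Y))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(folds != f)
    teIdx <- which(folds == f)
    set.seed(seed * 100 + f)
    nMon <- max(1, round(monitorFrac * length(trIdx)))
    mon <- sample(trIdx, nMon)
    fit <- setdiff(trIdx, mon)
    nrm <- fitNormalizer(X[fit, , drop = FALSE])
    Zfit <- applyNormalizer(nrm, X[fit, , drop = FALSE])
    Zmon <- applyNormalizer(nrm, X[mon, , drop = FALSE])
    Zte <- applyNormalizer(nrm, X[teIdx, , drop = FALSE])
    model <- annInit(ncol(X), nHidden, ncol(Y), seed = seed * 100 + f,
                     kinases = colnames(Y))
    cfg <- config
    cfg$shuffleSeed <- seed * 100 + f
    model <- annTrain(model, Zfit, Y[fit, , drop = FALSE], cfg,
                      Xval = Zmon, Yval = Y[mon, , drop = FALSE])
    model@normalizer <- nrm
    models[[f]] <- model
    P[teIdx, ] <- .annForwardMatrix(model, Zte)
  }
  list(scores = P, folds = folds, models = models)
}

#' Pooled confusion metrics of cross-validated scores
#'
#' Chooses a per-kinase decision threshold (max MCC) on the
#' cross-validated scores, applies it, and pools TP/FP/TN/FN across all
#' kinases and compounds the way panel-profiling reports tabulate them.
#' Kinases
#' with a single observed class are called all-inactive at threshold 0.5.
#'
#' @param scores cross-validated score matrix; @param labels 0/1 matrix.
#' @return list: `metrics` ([classificationMetrics()]), `thresholds`
#'   (per-kinase vector).
#' @export
cvPooledMetrics <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  nk <- ncol(scores)
  thr <- numeric(nk)
  calls <- matrix(0L, nrow(scores), nk, dimnames = dimnames(labels))
  for (j in seq_len(nk)) {
    l <- labels[, j]
    if (length(unique(l)) < 2 || length(unique(scores[, j])) < 2) {
      thr[j] <- 0.5
    } else {
      thr[j] <- chooseThreshold(scores[, j], l)$threshold
    }
    calls[, j] <- as.integer(scores[, j] >= thr[j])
  }
  co <- confusionCounts(as.integer(labels), as.integer(calls))
  list(metrics = classificationMetrics(co), thresholds = thr,
       calls = calls)
}
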