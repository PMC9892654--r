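#' Create a repeated holdout plan
#'
#' @param nReplicates number of train/test replicates (default 50).
#' @param testFraction held-out fraction (default 0.2, i.e. an 80/20
#'   split).
#' @param stratified stratify splits by response class (default TRUE).
#'   With few samples in the smallest class an unstratified split can
#'   leave a class out of training, which is an error at evaluation time.
#' @param seed integer seed from which the per-replicate split seeds are
#'   drawn; alternatively pass \code{splitSeeds} directly.
#' @param splitSeeds optional explicit vector of distinct integer seeds,
#'   one per replicate.
#' @return A \linkS4class{HoldoutPlan}.
#' @examples
#' HoldoutPlan(nReplicates = 10, seed = 7)
#' @export
HoldoutPlan <- function(nReplicates = 50L, testFraction = 0.2,
                        stratified = TRUE, seed = 1L, splitSeeds = NULL) {
  nReplicates <- as.integer(nReplicates)
  if (is.null(splitSeeds))
    splitSeeds <- withSeed(seed,
      sample.int(.Machine$integer.max - 1L, nReplicates))
  methods::new("HoldoutPlan", nReplicates = nReplicates,
               testFraction = testFraction, stratified = stratified,
               splitSeeds = as.integer(splitSeeds))
}

setMethod("show", "HoldoutPlan", function(object) {
  cat("HoldoutPlan:", object@nReplicates, "replicates,",
      sprintf("%.0f%%/%.0f%% split,", 100 * (1 - object@testFraction),
              100 * object@testFraction),
      if (object@stratified) "stratified" else "unstratified", "\n")
})

#' Test-set indices for every replicate of a plan
#'
#' Materialises the holdout splits a plan defines for a given label
#' vector. Stratified splits hold out \code{round(testFraction * n_c)}
#' samples of each class (at least 1, always leaving at least 2 in
#' training).
#'
#' @param plan a \linkS4class{HoldoutPlan}.
#' @param labels factor of per-sample response classes.
#' @return List of integer vectors, the test-sample indices per replicate.
#' @export
holdoutSplits <- function(plan, labels) {
  labels <- factor(labels)
  n <- length(labels)
  lapply(plan@splitSeeds, function(s) withSeed(s, {
    if (plan@stratified) {
      idx <- unlist(lapply(split(seq_len(n), labels), function(j) {
        nTest <- min(max(1L, round(plan@testFraction * length(j))),
                     length(j) - 2L)
        if (nTest < 1L)
          stop("class too small to stratify (needs >= 3 samples)")
        sample(j, nTest)
      }), use.names = FALSE)
      sort(idx)
    } else {
      sort(sample.int(n, max(1L, round(plan@testFraction * n))))
    }
  }))
}

# Per-class decision scores from libsvm pairwise decision values:
# column "A/B" is positive when A is favoured, so A gains +d and B -d.
pairwiseClassScores <- function(dv, classes) {
  scores <- matrix(0, nrow(dv), length(classes),
                   dimnames = list(NULL, classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1L]]
    scores[, pair[1L]] <- scores[, pair[1L]] + dv[, cn]
    scores[, pair[2L]] <- scores[, pair[2L]] - dv[, cn]
  }
  scores
}

#' Evaluate a feature set with a multi-class linear SVM
#'
#' The evaluation engine behind the whole discovery pipeline. For each
#' replicate of the plan the samples are split (stratified by class by
#' default), each feature is standardized to zero mean and unit variance
#' using training-set statistics only, a one-vs-one linear-kernel SVM
#' (cost 1) is fitted on the training set, and the held-out samples are
#' predicted. Accuracies, the summed confusion matrix, per-class
#' precision/sensitivity and pooled one-vs-rest AUCs are accumulated.
#' Deterministic given the plan.
#'
#' @param x a fully imputed \linkS4class{BiomarkerExperiment}.
#' @param features character vector of feature IDs to use as predictors.
#' @param plan a \linkS4class{HoldoutPlan}.
#' @param labels optional response factor; defaults to
#'   \code{responseLabels(x)}.
#' @param computeAuc compute per-class pooled AUCs (default TRUE); skip
#'   for speed in large search loops.
#' @return An \linkS4class{EvalReport}.
#' @examples
#' sim <- imputeMissing(simulateCohort(seed = 1), seed = 2)
#' plan <- HoldoutPlan(nReplicates = 5, seed = 3)
#' rep <- evaluateFeatures(sim, informativeFeatures(sim), plan)
#' meanAccuracy(rep)
#' @export
evaluateFeatures <- function(x, features, plan, labels = responseLabels(x),
                             computeAuc = TRUE) {
  m <- abundance(x)
  if (anyNA(m))
    stop("matrix contains missing values; impute first (imputeMissing)")
  if (length(features) == 0L) stop("'features' must be non-empty")
  unknown <- setdiff(features, rownames(m))
  if (length(unknown))
    stop("unknown feature ID: ", unknown[1L])
  labels <- droplevels(factor(labels))
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 samples")
  classes <- levels(labels)
  dat <- t(m[features, , drop = FALSE])   # samples x features
  splits <- holdoutSplits(plan, labels)

  acc <- numeric(plan@nReplicates)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  predList <- vector("list", plan@nReplicates)
  for (i in seq_len(plan@nReplicates)) {
    testIdx <- splits[[i]]
    trainIdx <- setdiff(seq_len(nrow(dat)), testIdx)
    trainY <- labels[trainIdx]
    if (nlevels(droplevels(trainY)) < length(classes))
      stop("a class is absent from the training split of replicate ", i,
           "; use a stratified plan")
    tr <- dat[trainIdx, , drop = FALSE]
    mu <- colMeans(tr)
    sg <- sqrt(colSums((tr - rep(mu, each = nrow(tr)))^2) / (nrow(tr) - 1L))
    sg[sg == 0] <- 1   # constant feature in training: leave it centred
    trainX <- t((t(tr) - mu) / sg)
    testX <- t((t(dat[testIdx, , drop = FALSE]) - mu) / sg)
    fit <- e1071::svm(x = trainX, y = trainY, kernel = "linear", cost = 1,
                      scale = FALSE)
    pr <- predict(fit, testX, decision.values = computeAuc)
    trueI <- as.integer(labels[testIdx])
    predI <- as.integer(factor(pr, levels = classes))
    acc[i] <- mean(predI == trueI)
    hits <- cbind(trueI, predI)
    for (r in seq_len(nrow(hits)))
      confusion[hits[r, 1L], hits[r, 2L]] <-
        confusion[hits[r, 1L], hits[r, 2L]] + 1L
    if (computeAuc) {
      dv <- attr(pr, "decision.values")
      sc <- pairwiseClassScores(dv, classes)
      predList[[i]] <- data.frame(replicate = i,
                                  sample_id = rownames(dat)[testIdx],
                                  true = as.character(labels[testIdx]),
                                  predicted = as.character(pr),
                                  sc, stringsAsFactors = FALSE,
                                  row.names = NULL)
    }
  }
  preds <- if (computeAuc) do.call(rbind, predList) else
    data.frame(replicate = integer(), sample_id = character(),
               true = character(), predicted = character())
  precision <- diag(confusion) / colSums(confusion)
  sensitivity <- diag(confusion) / rowSums(confusion)
  auc <- setNames(rep(NA_real_, length(classes)), classes)
  if (computeAuc) {
    for (cls in classes) {
      resp <- preds$true == cls
      if (length(unique(resp)) == 2L)
        auc[cls] <- as.numeric(pROC::auc(pROC::roc(
          response = resp, predictor = preds[[cls]],
          direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)))
    }
  }
  methods::new("EvalReport", features = as.character(features),
               perReplicateAccuracy = acc,
               confusion = unclass(confusion),
               precision = setNames(as.numeric(precision), classes),
               sensitivity = setNames(as.numeric(sensitivity), classes),
               auc = auc, predictions = preds)
}

#' Mean holdout accuracy of a report
#'
#' @param x an \linkS4class{EvalReport}.
#' @return Mean of the per-replicate test accuracies.
#' @export
#' @aliases meanAccuracy,EvalReport-method
#' @rdname meanAccuracy
setMethod("meanAccuracy", "EvalReport", function(x)
  mean(x@perReplicateAccuracy))

#' Accuracy summary (mean over replicates)
#'
#' @param report an \linkS4class{EvalReport}.
#' @return Numeric scalar, the mean per-replicate accuracy.
#' @export
accuracySummary <- function(report) meanAccuracy(report)

#' Per-replicate accuracies of a report
#'
#' @param report an \linkS4class{EvalReport}.
#' @return Numeric vector of test accuracies, one per replicate.
#' @export
replicateAccuracies <- function(report) report@perReplicateAccuracy

#' Summed confusion matrix of a report
#'
#' @param x an \linkS4class{EvalReport}.
#' @return Integer matrix, rows = true class, columns = predicted,
#'   summed over all replicates.
#' @export
#' @aliases confusionMatrix,EvalReport-method
#' @rdname confusionMatrix
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' Per-class metrics of a report
#'
#' @param x an \linkS4class{EvalReport}.
#' @return data.frame with per-class precision, sensitivity and pooled
#'   one-vs-rest AUC.
#' @export
#' @aliases classMetrics,EvalReport-method
#' @rdname classMetrics
setMethod("classMetrics", "EvalReport", function(x)
  data.frame(class = names(x@precision), precision = as.numeric(x@precision),
             sensitivity = as.numeric(x@sensitivity),
             auc = as.numeric(x@auc), row.names = NULL))

#' Pooled per-sample predictions of a report
#'
#' @param report an \linkS4class{EvalReport}.
#' @return data.frame of held-out predictions across replicates, with
#'   per-class decision scores.
#' @export
reportPredictions <- function(report) report@predictions

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", length(object@features), "features,",
      length(object@perReplicateAccuracy), "replicates\n")
  cat(sprintf("  mean accuracy: %.3f (sd %.3f)\n",
              mean(object@perReplicateAccuracy),
              sd(object@perReplicateAccuracy)))
  print(classMetrics(object))
})
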