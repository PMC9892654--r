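#' Greedy forward feature selection over importance-ranked features
#'
#' Single-pass greedy accretion: the model starts from the top-ranked
#' positive-impact feature alone, then walks once down the remaining
#' ranked features; each candidate is added to the model, the model is
#' re-evaluated under the shared holdout plan, and the candidate is kept
#' only if the mean accuracy strictly increases (an exact comparison on
#' the shared-seed estimate — candidates that leave accuracy unchanged
#' are skipped). Accepted-step accuracies are therefore strictly
#' increasing. The pass performs exactly one classifier evaluation per
#' ranked feature, so together with the preceding drop-out analysis the
#' whole selection costs at most 2n evaluations for n features — linear,
#' versus the quadratic n(n+1)/2 of classical forward selection.
#'
#' @param x a fully imputed \linkS4class{BiomarkerExperiment}.
#' @param rankedPositive character vector of candidate features with
#'   positive importance, in rank order (see
#'   \code{\link{positiveImpactFeatures}}). May be empty, yielding an
#'   empty trace.
#' @param plan a \linkS4class{HoldoutPlan}; use the same plan as the
#'   importance analysis so accuracies stay paired.
#' @param labels optional response factor; defaults to
#'   \code{responseLabels(x)}.
#' @return A \linkS4class{GffsTrace}.
#' @examples
#' sim <- imputeMissing(simulateCohort(nFeatures = 30, seed = 1), seed = 2)
#' plan <- HoldoutPlan(nReplicates = 10, seed = 3)
#' tr <- gffs(sim, informativeFeatures(sim), plan)
#' selectedFeatures(tr)
#' @export
gffs <- function(x, rankedPositive, plan, labels = responseLabels(x)) {
  steps <- data.frame(feature_id = character(), accuracy = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE)
  if (length(rankedPositive) == 0L)
    return(methods::new("GffsTrace", steps = steps, selected = character(),
                        finalAccuracy = NA_real_, modelEvaluations = 0L))
  evals <- 0L
  evalPanel <- function(panel) {
    evals <<- evals + 1L
    meanAccuracy(evaluateFeatures(x, panel, plan, labels,
                                  computeAuc = FALSE))
  }
  selected <- rankedPositive[1L]
  best <- evalPanel(selected)
  steps <- rbind(steps, data.frame(feature_id = selected, accuracy = best,
                                   accepted = TRUE))
  for (f in rankedPositive[-1L]) {
    acc <- evalPanel(c(selected, f))
    keep <- acc > best
    steps <- rbind(steps, data.frame(feature_id = f, accuracy = acc,
                                     accepted = keep))
    if (keep) {
      selected <- c(selected, f)
      best <- acc
    }
  }
  methods::new("GffsTrace", steps = steps, selected = selected,
               finalAccuracy = best, modelEvaluations = evals)
}

#' Features selected by a greedy forward pass
#'
#' @param x a \linkS4class{GffsTrace}.
#' @return Character vector of accepted features, in acceptance order.
#' @export
#' @aliases selectedFeatures,GffsTrace-method
#' @rdname selectedFeatures
setMethod("selectedFeatures", "GffsTrace", function(x) x@selected)

#' Number of classifier evaluations performed
#'
#' @param x a \linkS4class{GffsTrace}.
#' @return Integer evaluation count.
#' @export
#' @aliases modelEvaluations,GffsTrace-method
#' @rdname modelEvaluations
setMethod("modelEvaluations", "GffsTrace", function(x) x@modelEvaluations)

#' Steps of a greedy forward pass
#'
#' @param trace a \linkS4class{GffsTrace}.
#' @return data.frame with one row per considered candidate: feature,
#'   accuracy when added, accepted flag.
#' @export
gffsSteps <- function(trace) trace@steps

setMethod("show", "GffsTrace", function(object) {
  cat("GffsTrace:", nrow(object@steps), "candidates considered,",
      length(object@selected), "selected;",
      object@modelEvaluations, "model evaluations\n")
  if (length(object@selected))
    cat(sprintf("  final accuracy %.3f with panel: %s\n",
                object@finalAccuracy,
                paste(object@selected, collapse = ", ")))
})
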