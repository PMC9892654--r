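#' Drop-out importance score
#'
#' Relative accuracy loss when a feature is removed:
#' \code{IS = -(paDropout - paOriginal) / paOriginal}. Positive scores
#' mark features whose removal hurts the model (positive impact),
#' negative scores features whose removal helps, zero no impact.
#'
#' @param paOriginal accuracy of the reference model on the full feature
#'   pool (must be > 0).
#' @param paDropout accuracy of the model with the feature removed.
#' @return Numeric importance score(s).
#' @examples
#' importanceScore(0.77, 0.70)   # removal hurts: positive impact
#' @export
importanceScore <- function(paOriginal, paDropout) {
  if (any(paOriginal == 0))
    stop("reference accuracy is 0; the importance score is undefined")
  -(paDropout - paOriginal) / paOriginal
}

#' Paired feature drop-out importance analysis
#'
#' Evaluates the classifier on the full feature pool, then once per
#' feature with that feature removed, reusing the identical holdout
#' splits so the paired accuracies differ only through the dropped
#' feature. Features are scored with \code{\link{importanceScore}} and
#' returned sorted by score (descending; ties keep original pool order).
#'
#' @param x a fully imputed \linkS4class{BiomarkerExperiment}.
#' @param featurePool character vector of >= 2 feature IDs.
#' @param plan a \linkS4class{HoldoutPlan} shared by all evaluations.
#' @param labels optional response factor; defaults to
#'   \code{responseLabels(x)}.
#' @return An \linkS4class{ImportanceTable}.
#' @seealso \code{\link{gffs}}
#' @export
importanceScores <- function(x, featurePool, plan,
                             labels = responseLabels(x)) {
  if (length(featurePool) < 2L)
    stop("the feature pool must contain at least 2 features")
  paO <- meanAccuracy(evaluateFeatures(x, featurePool, plan, labels,
                                       computeAuc = FALSE))
  if (paO == 0)
    stop("reference accuracy is 0; the importance score is undefined")
  paI <- vapply(seq_along(featurePool), function(i)
    meanAccuracy(evaluateFeatures(x, featurePool[-i], plan, labels,
                                  computeAuc = FALSE)), numeric(1))
  entries <- data.frame(feature_id = featurePool,
                        IS = importanceScore(paO, paI),
                        pa_dropout = paI, pa_original = paO,
                        stringsAsFactors = FALSE)
  ord <- order(-entries$IS, seq_len(nrow(entries)))
  methods::new("ImportanceTable", entries = entries[ord, , drop = FALSE])
}

#' Importance table as a data.frame
#'
#' @param x an \linkS4class{ImportanceTable}.
#' @param row.names,optional,... see \code{\link[base]{as.data.frame}}.
#' @return data.frame sorted by IS descending with columns feature_id,
#'   IS, pa_dropout, pa_original.
#' @exportS3Method base::as.data.frame
#' @export as.data.frame.ImportanceTable
as.data.frame.ImportanceTable <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  df <- x@entries
  rownames(df) <- row.names
  df
}

#' Positive-impact features of an importance table
#'
#' @param table an \linkS4class{ImportanceTable}.
#' @return Character vector of feature IDs with IS > 0, in rank order —
#'   the candidate pool for \code{\link{gffs}}.
#' @export
positiveImpactFeatures <- function(table) {
  e <- table@entries
  e$feature_id[e$IS > 0]
}

setMethod("show", "ImportanceTable", function(object) {
  cat("ImportanceTable:", nrow(object@entries), "features, reference",
      sprintf("accuracy %.3f\n", object@entries$pa_original[1L]))
  print(head(object@entries, 5), row.names = FALSE)
  if (nrow(object@entries) > 5) cat("  ...\n")
})
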