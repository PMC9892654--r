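#' @import methods
#' @importFrom stats pf quantile median rnorm runif sd var predict setNames
#' @importFrom utils combn head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Response class levels
#'
#' The three drug-response classes used throughout the package, in their
#' canonical order: responders (RD), non-responders (NR) and poor
#' responders (PR).
#'
#' @return Character vector of length three.
#' @examples
#' responseClasses()
#' @export
responseClasses <- function() c("RD", "NR", "PR")

#' BiomarkerExperiment: expression matrix plus response labels
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one
#' \code{"abundance"} assay (features x samples, real-valued, \code{NA}
#' marks missing/undetectable measurements) and, optionally, per-sample
#' drug-response information in \code{colData}: a \code{response} factor
#' over \code{RD}/\code{NR}/\code{PR} and/or a numeric \code{log2Ki67}
#' column (log2 fold change in Ki67 positivity, treatment vs vehicle).
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso \code{\link{BiomarkerExperiment}} (constructor),
#'   \code{\link{abundance}}, \code{\link{responseLabels}}
#' @exportClass BiomarkerExperiment
setClass("BiomarkerExperiment", contains = "SummarizedExperiment")

setValidity("BiomarkerExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (!is.numeric(a))
      msg <- c(msg, "'abundance' assay must be numeric")
    else if (any(!is.finite(a) & !is.na(a)))
      msg <- c(msg, "non-missing abundances must be finite")
  }
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "feature IDs must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample IDs must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if ("response" %in% names(cd)) {
    r <- cd$response
    if (!is.factor(r) || !all(levels(r) %in% responseClasses()))
      msg <- c(msg, "colData$response must be a factor over RD/NR/PR")
    if (anyNA(r))
      msg <- c(msg, "colData$response must not contain NA")
  }
  if ("log2Ki67" %in% names(cd) && !is.numeric(cd$log2Ki67))
    msg <- c(msg, "colData$log2Ki67 must be numeric")
  if (length(msg)) msg else TRUE
})

#' Repeated stratified holdout plan
#'
#' Fixes the train/test protocol under which every model in a run is
#' evaluated: the number of replicate splits, the held-out fraction,
#' whether splits are stratified by response class, and one RNG seed per
#' replicate. Reusing a single plan across drop-out, greedy-selection and
#' panel evaluations pairs the accuracy estimates, so differences reflect
#' the features rather than split noise.
#'
#' @slot nReplicates integer, number of holdout replicates.
#' @slot testFraction numeric in (0,1), held-out fraction.
#' @slot stratified logical, stratify splits by class.
#' @slot splitSeeds integer vector, one distinct seed per replicate.
#' @exportClass HoldoutPlan
setClass("HoldoutPlan",
  representation(nReplicates = "integer", testFraction = "numeric",
                 stratified = "logical", splitSeeds = "integer"))

setValidity("HoldoutPlan", function(object) {
  msg <- character()
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must be in (0, 1)")
  if (length(object@splitSeeds) != object@nReplicates)
    msg <- c(msg, "need one split seed per replicate")
  if (anyDuplicated(object@splitSeeds))
    msg <- c(msg, "split seeds must be distinct")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation report
#'
#' The result of evaluating one feature set under a
#' \linkS4class{HoldoutPlan}: the per-replicate test accuracies, the
#' confusion matrix summed over replicates (rows = true class, columns =
#' predicted), per-class precision/sensitivity derived from it, per-class
#' one-vs-rest AUC pooled over replicates, and the pooled per-sample
#' prediction table.
#'
#' @slot features character, the evaluated feature IDs.
#' @slot perReplicateAccuracy numeric vector in [0,1].
#' @slot confusion integer matrix, true x predicted, summed over replicates.
#' @slot precision,sensitivity,auc named numeric, one value per class
#'   (NA where undefined, e.g. a class never predicted).
#' @slot predictions data.frame with columns replicate, sample_id, true,
#'   predicted and one decision-score column per class.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(features = "character", perReplicateAccuracy = "numeric",
                 confusion = "matrix", precision = "numeric",
                 sensitivity = "numeric", auc = "numeric",
                 predictions = "data.frame"))

#' Drop-out importance table
#'
#' Per-feature importance scores from the paired feature drop-out
#' analysis, sorted by score (descending, ties broken by original pool
#' order). Each row records the accuracy of the drop-out model missing
#' that feature (\code{pa_dropout}) and the shared full-pool reference
#' accuracy (\code{pa_original}).
#'
#' @slot entries data.frame with columns feature_id, IS, pa_dropout,
#'   pa_original.
#' @exportClass ImportanceTable
setClass("ImportanceTable", representation(entries = "data.frame"))

setValidity("ImportanceTable", function(object) {
  e <- object@entries
  need <- c("feature_id", "IS", "pa_dropout", "pa_original")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e) && length(unique(e$pa_original)) != 1L)
    return("pa_original must be identical across entries")
  if (nrow(e) &&
      any(abs(e$IS - (-(e$pa_dropout - e$pa_original) / e$pa_original)) > 1e-12))
    return("IS inconsistent with -(pa_dropout - pa_original)/pa_original")
  TRUE
})

#' Greedy forward feature selection trace
#'
#' The full audit trail of one greedy forward pass: every candidate
#' considered with the accuracy the model reached when the candidate was
#' added, whether it was accepted, the resulting ordered selection, the
#' final accuracy and the number of classifier evaluations performed.
#'
#' @slot steps data.frame with columns feature_id, accuracy, accepted.
#' @slot selected character, accepted features in acceptance order.
#' @slot finalAccuracy numeric.
#' @slot modelEvaluations integer, classifier evaluations performed.
#' @exportClass GffsTrace
setClass("GffsTrace",
  representation(steps = "data.frame", selected = "character",
                 finalAccuracy = "numeric", modelEvaluations = "integer"))

#' Sum-of-products Boolean function
#'
#' A Boolean function over \code{nVars} binary variables in two-level
#' sum-of-products form. Terms are the rows of an integer matrix over
#' \{0, 1, NA\}: 0 a complemented literal (variable low), 1 an
#' uncomplemented literal (variable high), NA a don't-care position. A
#' zero-row matrix is the constant-0 function; a single all-NA row is the
#' constant-1 function.
#'
#' @slot nVars integer, number of variables.
#' @slot terms integer matrix, one product term per row.
#' @exportClass SopFunction
setClass("SopFunction",
  representation(nVars = "integer", terms = "matrix"))

setValidity("SopFunction", function(object) {
  t <- object@terms
  if (ncol(t) != object@nVars)
    return("terms must have nVars columns")
  v <- t[!is.na(t)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("term literals must be 0, 1 or NA (don't-care)")
  TRUE
})

#' Binarized expression matrix
#'
#' The result of discretizing a \linkS4class{BiomarkerExperiment}:
#' an integer matrix over \{0, 1, NA\} where NA marks values falling in
#' the indeterminate band of a quantile-band scheme (the median scheme
#' produces no NA), plus a record of the scheme used.
#'
#' @slot bits integer matrix (features x samples) over \{0, 1, NA\}.
#' @slot scheme list describing the binarization scheme.
#' @exportClass BinarizedMatrix
setClass("BinarizedMatrix",
  representation(bits = "matrix", scheme = "list"))

#' Response-group signature set
#'
#' The minimized expression signatures of one response group: product
#' terms over the binarized biomarkers with per-signature coverage (the
#' fraction of the group's samples whose bit pattern satisfies the term).
#' Signature IDs are assigned in ascending term order for determinism.
#'
#' @slot group character, one of RD/NR/PR.
#' @slot variables character, biomarker IDs in variable order.
#' @slot terms integer matrix over \{0, 1, NA\}, one signature per row.
#' @slot coverage numeric vector in (0, 1], per signature.
#' @exportClass SignatureSet
setClass("SignatureSet",
  representation(group = "character", variables = "character",
                 terms = "matrix", coverage = "numeric"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (!object@group %in% responseClasses())
    msg <- c(msg, "group must be one of RD/NR/PR")
  if (ncol(object@terms) != length(object@variables))
    msg <- c(msg, "terms must have one column per variable")
  if (nrow(object@terms) != length(object@coverage))
    msg <- c(msg, "need one coverage value per signature")
  if (length(object@coverage) &&
      (any(object@coverage <= 0) || any(object@coverage > 1)))
    msg <- c(msg, "coverage must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
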