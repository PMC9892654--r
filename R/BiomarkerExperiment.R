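#' Construct a BiomarkerExperiment
#'
#' Bundle a features x samples abundance matrix with optional per-sample
#' response information into a \linkS4class{BiomarkerExperiment}. `NA`
#' entries of `abundance` represent missing (undetectable) measurements;
#' see \code{\link{imputeMissing}}.
#'
#' @param abundance numeric matrix, features in rows, samples in columns,
#'   with unique row and column names.
#' @param response optional per-sample response class; character or factor
#'   over \code{RD}/\code{NR}/\code{PR}.
#' @param log2Ki67 optional numeric vector of per-sample log2 fold changes
#'   in Ki67 positivity (treatment vs vehicle). When supplied without
#'   `response`, classes are derived via \code{\link{labelFromKi67}}.
#' @param metadata optional list stored as experiment metadata.
#' @return A \linkS4class{BiomarkerExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' be <- BiomarkerExperiment(m, response = c("RD", "RD", "NR", "PR"))
#' abundance(be)
#' responseLabels(be)
#' @export
BiomarkerExperiment <- function(abundance, response = NULL, log2Ki67 = NULL,
                                metadata = list()) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(abundance))
  if (!is.null(log2Ki67)) {
    stopifnot(length(log2Ki67) == ncol(abundance))
    cd$log2Ki67 <- as.numeric(log2Ki67)
    if (is.null(response)) response <- labelFromKi67(log2Ki67)
  }
  if (!is.null(response)) {
    stopifnot(length(response) == ncol(abundance))
    cd$response <- factor(as.character(response), levels = responseClasses())
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd, metadata = metadata)
  methods::new("BiomarkerExperiment", se)
}

#' Abundance matrix accessor
#'
#' @param x a \linkS4class{BiomarkerExperiment}.
#' @param ... unused.
#' @return Numeric matrix of abundances (NA = missing).
#' @export
#' @aliases abundance,BiomarkerExperiment-method
#' @rdname abundance
setMethod("abundance", "BiomarkerExperiment", function(x, ...)
  SummarizedExperiment::assay(x, "abundance"))

#' Response label accessor
#'
#' @param x a \linkS4class{BiomarkerExperiment}.
#' @param value factor or character over RD/NR/PR.
#' @param ... unused.
#' @return Factor of per-sample response classes (levels RD, NR, PR), or
#'   NULL when the experiment carries no labels.
#' @export
#' @aliases responseLabels,BiomarkerExperiment-method
#'   responseLabels<-,BiomarkerExperiment-method
#' @rdname responseLabels
setMethod("responseLabels", "BiomarkerExperiment", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  if ("response" %in% names(cd)) cd$response else NULL
})

#' @export
#' @rdname responseLabels
setReplaceMethod("responseLabels", "BiomarkerExperiment", function(x, value) {
  SummarizedExperiment::colData(x)$response <-
    factor(as.character(value), levels = responseClasses())
  methods::validObject(x)
  x
})

#' Ground-truth informative features of a synthetic cohort
#'
#' @param x a \linkS4class{BiomarkerExperiment} produced by
#'   \code{\link{simulateCohort}}.
#' @return Character vector of planted informative feature IDs (NULL for
#'   experiments without ground truth).
#' @export
#' @aliases informativeFeatures,BiomarkerExperiment-method
#' @rdname informativeFeatures
setMethod("informativeFeatures", "BiomarkerExperiment", function(x)
  S4Vectors::metadata(x)$informative)

#' Missingness mask
#'
#' @param x a \linkS4class{BiomarkerExperiment}.
#' @return Logical matrix, TRUE where the abundance is missing.
#' @examples
#' m <- matrix(c(1, NA, 3, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("S1", "S2")))
#' isMissing(BiomarkerExperiment(m))
#' @export
isMissing <- function(x) is.na(abundance(x))

setMethod("show", "BiomarkerExperiment", function(object) {
  cat("BiomarkerExperiment:", nrow(object), "features x",
      ncol(object), "samples\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "abundance")))
  cat("  missing values:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / max(1, prod(dim(object)))))
  r <- responseLabels(object)
  if (!is.null(r)) {
    tab <- table(r)
    cat("  response:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  inf <- informativeFeatures(object)
  if (!is.null(inf))
    cat("  planted informative features:", length(inf), "\n")
})
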