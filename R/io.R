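# Tokens treated as missing values when parsing expression tables
# (case-insensitive, plus the empty cell).
missingTokens <- c("", "na", "nan")

withSeed <- function(seed, expr) {
  # run expr under set.seed(seed) without leaking global RNG state
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

guessDialect <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
}

#' Read an expression matrix from TSV/CSV
#'
#' Parses a delimited text table whose first row holds sample IDs and
#' first column feature IDs; remaining cells are real-valued abundances.
#' Empty cells, \code{NA} and \code{NaN} (case-insensitive) are read as
#' missing. Input row and column order is preserved.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} or \code{"csv"}; default guessed from the
#'   file extension (.csv = comma, anything else = tab).
#' @return A \linkS4class{BiomarkerExperiment} with missing cells as NA.
#' @details Duplicate feature or sample IDs, ragged rows and non-numeric
#'   cells are errors that name the offending ID, line or coordinate.
#' @seealso \code{\link{writeExpression}}, \code{\link{imputeMissing}}
#' @export
readExpression <- function(path, dialect = guessDialect(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2L) stop("expression table needs a header and data rows")
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1L]]
  # header may or may not carry a leading stub over the feature-ID column
  body1 <- cells[[2L]]
  sampleIds <- if (length(header) == length(body1)) header[-1L] else header
  ncols <- length(sampleIds) + 1L
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ID: ",
         sampleIds[duplicated(sampleIds)][1L])
  featureIds <- character(length(cells) - 1L)
  vals <- matrix(NA_real_, length(cells) - 1L, length(sampleIds))
  for (i in seq_along(featureIds)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncols)
      stop("ragged row at line ", i + 1L, ": expected ", ncols,
           " fields, found ", length(row))
    featureIds[i] <- row[1L]
    for (j in seq_along(sampleIds)) {
      tok <- trimws(row[j + 1L])
      if (tolower(tok) %in% missingTokens) next
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v))
        stop("non-numeric cell at row ", i, " (feature '", row[1L],
             "'), column ", j, " (sample '", sampleIds[j], "'): '", tok, "'")
      vals[i, j] <- v
    }
  }
  if (anyDuplicated(featureIds))
    stop("duplicate feature ID: ", featureIds[duplicated(featureIds)][1L])
  dimnames(vals) <- list(featureIds, sampleIds)
  BiomarkerExperiment(vals)
}

#' Write an expression matrix to TSV/CSV
#'
#' Serializes abundances with full precision (missing cells as \code{NA})
#' so that \code{readExpression(writeExpression(x))} round-trips values,
#' IDs and order exactly.
#'
#' @param x a \linkS4class{BiomarkerExperiment} or numeric matrix with
#'   dimnames.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}; default from extension.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(x, path, dialect = guessDialect(path)) {
  m <- if (methods::is(x, "BiomarkerExperiment")) abundance(x) else as.matrix(x)
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"
  fmt <- function(v) ifelse(is.na(v), "NA",
                            formatC(v, digits = 17, format = "g"))
  lines <- c(paste(c("feature_id", colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = sep),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample response labels
#'
#' Reads a two-column CSV of either (\code{sample_id}, \code{class}) with
#' classes in RD/NR/PR, or (\code{sample_id}, \code{log2_ki67_fc}) from
#' which classes are derived with \code{\link{labelFromKi67}}.
#'
#' @param path path to the CSV.
#' @return data.frame with columns \code{sample_id}, \code{class}
#'   (factor RD/NR/PR) and, when fold changes were given,
#'   \code{log2_ki67_fc}.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs two columns")
  out <- data.frame(sample_id = as.character(df[[1L]]),
                    stringsAsFactors = FALSE)
  second <- df[[2L]]
  if (is.numeric(second)) {
    out$log2_ki67_fc <- second
    out$class <- labelFromKi67(second)
  } else {
    cls <- as.character(second)
    bad <- setdiff(unique(cls), responseClasses())
    if (length(bad)) stop("unknown response class: ", bad[1L])
    out$class <- factor(cls, levels = responseClasses())
  }
  out
}

#' Impute missing abundances with uniform random values
#'
#' Replaces every missing (NA) abundance with an independent draw from
#' Uniform(\code{low}, \code{high}); non-missing cells are untouched. The
#' default (0, 1) band reflects measurements below the minimal detectable
#' amount (scaled to 1).
#'
#' @param x a \linkS4class{BiomarkerExperiment}.
#' @param low,high bounds of the uniform distribution; \code{low < high}.
#' @param seed integer seed making the imputation reproducible.
#' @return The experiment with a complete abundance assay.
#' @examples
#' m <- matrix(c(1, NA, 3, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("S1", "S2")))
#' be <- imputeMissing(BiomarkerExperiment(m), seed = 1)
#' any(isMissing(be))
#' @export
imputeMissing <- function(x, low = 0, high = 1, seed) {
  if (low >= high) stop("'low' must be strictly less than 'high'")
  a <- abundance(x)
  idx <- which(is.na(a))
  if (length(idx) == 0L) return(x)
  a[idx] <- withSeed(seed, runif(length(idx), low, high))
  SummarizedExperiment::assay(x, "abundance") <- a
  methods::validObject(x)
  x
}

#' Derive response classes from Ki67 log2 fold changes
#'
#' Classifies samples from the log2 fold change in Ki67 positivity under
#' treatment: a two-fold or greater decrease (log2 fc <= -1) marks a
#' responder (RD), a two-fold or greater increase (log2 fc >= +1) a poor
#' responder (PR), and anything in between a non-responder (NR). The
#' thresholds are closed: values exactly at -1 or +1 take the outer class.
#'
#' @param fc numeric vector of log2 Ki67 fold changes (finite).
#' @return Factor with levels RD, NR, PR.
#' @examples
#' labelFromKi67(c(-1.5, 0, 1.5))
#' @export
labelFromKi67 <- function(fc) {
  fc <- as.numeric(fc)
  if (any(!is.finite(fc)))
    stop("all log2 Ki67 fold changes must be finite")
  cls <- ifelse(fc <= -1, "RD", ifelse(fc >= 1, "PR", "NR"))
  factor(cls, levels = responseClasses())
}
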