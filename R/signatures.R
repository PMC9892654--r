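#' Truth table of one response group
#'
#' Collects the distinct binarized expression patterns observed among a
#' group's samples. Each distinct pattern is one minterm of the group's
#' Boolean function; pattern frequencies are the fractions of the
#' group's samples showing each pattern (they sum to 1).
#'
#' @param b a \linkS4class{BinarizedMatrix} without indeterminate cells
#'   (median scheme) restricted to the biomarker panel.
#' @param labels factor of per-sample response classes, aligned with the
#'   columns of \code{b}.
#' @param group one of \code{"RD"}, \code{"NR"}, \code{"PR"}.
#' @return List with \code{minterms} (0/1 matrix, one pattern per row,
#'   columns = features), \code{counts} and \code{frequencies}.
#' @export
groupTruthTable <- function(b, labels, group) {
  bm <- bits(b)
  labels <- factor(labels, levels = responseClasses())
  if (length(labels) != ncol(bm)) stop("need one label per sample")
  group <- match.arg(group, responseClasses())
  sel <- which(labels == group)
  if (length(sel) == 0L) stop("group ", group, " has no samples")
  pat <- t(bm[, sel, drop = FALSE])
  if (anyNA(pat))
    stop("indeterminate bits in group ", group,
         "; derive truth tables under the median scheme")
  keys <- apply(pat, 1L, paste, collapse = "")
  tab <- table(keys)
  uniq <- pat[!duplicated(keys), , drop = FALSE]
  uniqKeys <- keys[!duplicated(keys)]
  ord <- order(uniqKeys)
  uniq <- uniq[ord, , drop = FALSE]
  counts <- as.integer(tab[uniqKeys[ord]])
  rownames(uniq) <- NULL
  list(minterms = uniq, counts = counts,
       frequencies = counts / length(sel))
}

#' Derive per-group expression signatures
#'
#' The discovery direction of the signature pipeline: for each response
#' group present, the group's observed binary expression patterns are
#' taken as the minterms of a Boolean function, which is minimized
#' exactly (\code{\link{minimizeBoolean}}); each product term of the
#' minimized cover becomes one expression signature. A signature's
#' coverage is the fraction of the group's samples whose pattern
#' satisfies it (one sample can satisfy several signatures). Signature
#' IDs are assigned in ascending term order. Because the minimized
#' function is equivalent to the observed pattern set, every group
#' sample satisfies at least one of its group's signatures.
#'
#' A bit pattern observed in more than one group produces overlapping
#' signatures; this is reported as a warning, not an error.
#'
#' @param b a \linkS4class{BinarizedMatrix} (median scheme) over the
#'   biomarker panel.
#' @param labels factor of response classes aligned with the samples.
#' @return Named list of \linkS4class{SignatureSet}, one per group
#'   present in \code{labels}.
#' @examples
#' sim <- imputeMissing(simulateCohort(nFeatures = 20, seed = 1), seed = 2)
#' b <- binarize(sim)
#' sigs <- deriveSignatures(b, responseLabels(sim))
#' sigs$RD
#' @export
deriveSignatures <- function(b, labels) {
  bm <- bits(b)
  labels <- factor(labels, levels = responseClasses())
  groups <- intersect(responseClasses(), levels(droplevels(labels)))
  tables <- lapply(groups, function(g) groupTruthTable(b, labels, g))
  names(tables) <- groups
  # cross-group pattern collisions
  allKeys <- lapply(tables, function(tt)
    apply(tt$minterms, 1L, paste, collapse = ""))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    shared <- intersect(allKeys[[i]], allKeys[[j]])
    if (length(shared))
      warning("expression pattern(s) ", paste(shared, collapse = ", "),
              " observed in both ", groups[j], " and ", groups[i],
              "; the groups' signatures will overlap", call. = FALSE)
  }
  out <- lapply(groups, function(g) {
    tt <- tables[[g]]
    f <- minimizeBoolean(tt$minterms)
    terms <- sopTerms(f)
    pat <- tt$minterms
    cov <- vapply(seq_len(nrow(terms)), function(k) {
      hit <- vapply(seq_len(nrow(pat)), function(r)
        matchTerm(pat[r, ], terms[k, ]), logical(1))
      sum(tt$counts[hit]) / sum(tt$counts)
    }, numeric(1))
    methods::new("SignatureSet", group = g, variables = rownames(bm),
                 terms = terms, coverage = cov)
  })
  names(out) <- groups
  out
}

#' Match a sample's bit pattern against a product term
#'
#' TRUE iff every literal the term specifies is satisfied by the sample.
#' Don't-care positions of the term are always satisfied, and an
#' indeterminate (NA) sample bit is *consistent with* either literal
#' value, so it satisfies the term too.
#'
#' @param sampleBits vector over \{0, 1, NA\}.
#' @param term integer vector over \{0, 1, NA\} of the same length.
#' @return Logical scalar.
#' @examples
#' matchTerm(c(0, 1, 1), c(0, NA, 1))   # A'C satisfied
#' matchTerm(c(1, 1, 1), c(0, NA, 1))   # A literal violated
#' @export
matchTerm <- function(sampleBits, term) {
  if (length(sampleBits) != length(term))
    stop("sample pattern and term have different lengths")
  spec <- !is.na(term) & !is.na(sampleBits)
  all(sampleBits[spec] == term[spec])
}

#' Predict response class from expression signatures
#'
#' Matches each sample's binarized biomarker pattern against the
#' signature sets of the three response groups and reports every group
#' with at least one matching signature. A singleton set is an
#' unambiguous call; an empty result is an explicit "no call"; matches
#' in several groups are reported as-is, with no forced single call.
#'
#' @param b a \linkS4class{BinarizedMatrix} of the new cohort over the
#'   same biomarkers (any scheme; indeterminate bits match under
#'   consistent-with semantics), or a single sample's bit vector.
#' @param signatureSets named list of \linkS4class{SignatureSet} as
#'   returned by \code{\link{deriveSignatures}}.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{predicted} (comma-joined group names, \code{""} for no call),
#'   \code{n_groups}, and \code{matched} (list column of named integer
#'   vectors of matched signature IDs per group).
#' @export
predictResponse <- function(b, signatureSets) {
  bm <- if (methods::is(b, "BinarizedMatrix")) bits(b)
        else matrix(b, ncol = 1L,
                    dimnames = list(names(b), "sample"))
  vars <- signatureSets[[1L]]@variables
  if (!all(vars %in% rownames(bm)))
    stop("binarized matrix lacks biomarker(s): ",
         paste(setdiff(vars, rownames(bm)), collapse = ", "))
  bm <- bm[vars, , drop = FALSE]
  rows <- lapply(seq_len(ncol(bm)), function(j) {
    pattern <- bm[, j]
    matched <- lapply(signatureSets, function(ss) {
      which(vapply(seq_len(nrow(ss@terms)), function(k)
        matchTerm(pattern, ss@terms[k, ]), logical(1)))
    })
    groups <- names(matched)[vapply(matched, length, integer(1)) > 0]
    data.frame(sample_id = colnames(bm)[j],
               predicted = paste(groups, collapse = ","),
               n_groups = length(groups), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$matched <- lapply(seq_len(ncol(bm)), function(j) {
    pattern <- bm[, j]
    lapply(signatureSets, function(ss)
      which(vapply(seq_len(nrow(ss@terms)), function(k)
        matchTerm(pattern, ss@terms[k, ]), logical(1))))
  })
  out
}

#' @export
#' @rdname coverage-accessors
#' @aliases signatureCoverage,SignatureSet-method
#'   signatureGroup,SignatureSet-method
#' @param x a \linkS4class{SignatureSet}.
setMethod("signatureCoverage", "SignatureSet", function(x)
  setNames(x@coverage, seq_along(x@coverage)))

#' @export
#' @rdname coverage-accessors
setMethod("signatureGroup", "SignatureSet", function(x) x@group)

#' Terms of a signature set
#'
#' @param x a \linkS4class{SignatureSet}.
#' @return Integer matrix over \{0, 1, NA\}, one signature per row, in
#'   ascending term order (= signature ID order).
#' @export
signatureTerms <- function(x) x@terms

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet for group", object@group, "-",
      nrow(object@terms), "signatures over",
      paste(object@variables, collapse = ", "), "\n")
  for (k in seq_len(nrow(object@terms)))
    cat(sprintf("  ID %d: %-30s coverage %.1f%%\n", k,
                formatTerm(object@terms[k, ], object@variables),
                100 * object@coverage[k]))
})

#' Write signature sets to JSON
#'
#' Serializes the variable order, binarization scheme and per-group
#' signature terms/coverages in a versioned, stable schema (don't-care
#' literals as null).
#'
#' @param signatureSets named list of \linkS4class{SignatureSet}.
#' @param path output path.
#' @param scheme optional binarization scheme list to record.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readSignatures}}
#' @export
writeSignatures <- function(signatureSets, path, scheme = medianScheme()) {
  obj <- list(
    schema_version = 1L,
    variables = signatureSets[[1L]]@variables,
    scheme = scheme,
    groups = lapply(signatureSets, function(ss) list(
      terms = lapply(seq_len(nrow(ss@terms)), function(k)
        as.list(ss@terms[k, ])),
      coverage = ss@coverage)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read signature sets from JSON
#'
#' @param path path written by \code{\link{writeSignatures}}.
#' @return Named list of \linkS4class{SignatureSet} (the recorded scheme
#'   is attached as attribute \code{"scheme"}).
#' @export
readSignatures <- function(path) {
  obj <- jsonlite::read_json(path)
  vars <- unlist(obj$variables)
  out <- lapply(names(obj$groups), function(g) {
    gr <- obj$groups[[g]]
    terms <- do.call(rbind, lapply(gr$terms, function(t)
      vapply(t, function(v) if (is.null(v)) NA_integer_
             else as.integer(v), integer(1))))
    storage.mode(terms) <- "integer"
    methods::new("SignatureSet", group = g, variables = vars,
                 terms = terms, coverage = as.numeric(unlist(gr$coverage)))
  })
  names(out) <- names(obj$groups)
  attr(out, "scheme") <- obj$scheme
  out
}
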