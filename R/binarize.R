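#' Quantile-band binarization scheme
#'
#' Describes the scheme used for noisy external cohorts: per feature,
#' values below the \code{low} quantile binarize to 0, above the
#' \code{high} quantile to 1, and the band in between is left
#' indeterminate (NA), to be matched with consistent-with semantics.
#'
#' @param low,high quantile cut-offs, 0 <= low < high <= 1 (defaults 0.3
#'   and 0.7).
#' @return A scheme list accepted by \code{\link{binarize}}.
#' @export
quantileBand <- function(low = 0.3, high = 0.7) {
  if (low < 0 || high > 1 || low >= high)
    stop("need 0 <= low < high <= 1")
  list(type = "quantile_band", low = low, high = high)
}

medianScheme <- function() list(type = "median")

#' Binarize an expression matrix
#'
#' Discretizes each feature's expression into low (0) / high (1) calls.
#' Under the median scheme each feature row is normalized to its median
#' across samples; normalized values > 1 become 1 and values <= 1 become
#' 0 (a value exactly at the median maps to 0 — the rule is configurable
#' via \code{tieHigh}). Under a \code{\link{quantileBand}} scheme, values
#' strictly below the low quantile become 0, strictly above the high
#' quantile become 1, and the rest are indeterminate (NA). Quantiles are
#' linear-interpolation sample quantiles. Both schemes are deterministic
#' and invariant to positive rescaling of a feature.
#'
#' @param x a fully imputed \linkS4class{BiomarkerExperiment} or numeric
#'   matrix (features x samples).
#' @param scheme \code{"median"} (default) or a \code{\link{quantileBand}}.
#' @param tieHigh if TRUE, a value exactly equal to the feature median
#'   maps to 1 instead of 0 (median scheme only).
#' @return A \linkS4class{BinarizedMatrix}.
#' @examples
#' m <- rbind(P1 = c(1, 2, 8, 9))
#' colnames(m) <- paste0("S", 1:4)
#' bits(binarize(m))   # 0 0 1 1
#' @export
binarize <- function(x, scheme = "median", tieHigh = FALSE) {
  m <- if (methods::is(x, "BiomarkerExperiment")) abundance(x) else as.matrix(x)
  if (anyNA(m))
    stop("matrix contains missing values; impute first (imputeMissing)")
  if (is.character(scheme) && identical(scheme, "median"))
    scheme <- medianScheme()
  b <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (scheme$type == "median") {
    for (i in seq_len(nrow(m))) {
      med <- median(m[i, ])
      if (med <= 0)
        stop("non-positive median for feature '", rownames(m)[i],
             "'; the median scheme requires positive medians")
      norm <- m[i, ] / med
      b[i, ] <- if (tieHigh) as.integer(norm >= 1) else as.integer(norm > 1)
    }
  } else if (scheme$type == "quantile_band") {
    for (i in seq_len(nrow(m))) {
      q <- quantile(m[i, ], c(scheme$low, scheme$high), type = 7,
                    names = FALSE)
      b[i, ] <- ifelse(m[i, ] < q[1L], 0L,
                       ifelse(m[i, ] > q[2L], 1L, NA_integer_))
    }
  } else stop("unknown binarization scheme: ", scheme$type)
  methods::new("BinarizedMatrix", bits = b, scheme = scheme)
}

#' Bit matrix of a binarized experiment
#'
#' @param x a \linkS4class{BinarizedMatrix}.
#' @return Integer matrix over \{0, 1, NA\} (NA = indeterminate).
#' @export
#' @aliases bits,BinarizedMatrix-method
#' @rdname bits
setMethod("bits", "BinarizedMatrix", function(x) x@bits)

#' Binarization scheme of a binarized experiment
#'
#' @param x a \linkS4class{BinarizedMatrix}.
#' @return The scheme list.
#' @export
binarizationScheme <- function(x) x@scheme

setMethod("show", "BinarizedMatrix", function(object) {
  cat("BinarizedMatrix:", nrow(object@bits), "features x",
      ncol(object@bits), "samples, scheme:", object@scheme$type, "\n")
  ind <- sum(is.na(object@bits))
  if (ind) cat("  indeterminate cells:", ind, "\n")
})
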