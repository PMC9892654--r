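#' One-way ANOVA scan across features
#'
#' Classical one-way fixed-effects F-test of each feature's abundance
#' across the response groups, computed row-wise from explicit sums of
#' squares. Degenerate features are handled by convention: when the
#' within-group variance is zero, p = 0 (F = Inf) if the group means
#' differ and p = 1 (F = 0) if every value is identical.
#'
#' @param x a fully imputed \linkS4class{BiomarkerExperiment}.
#' @param labels optional factor of response classes; defaults to
#'   \code{responseLabels(x)}.
#' @param log2 if TRUE, test log2-transformed abundances.
#' @return data.frame with one row per feature (input order preserved):
#'   \code{feature_id}, \code{f_statistic}, \code{p_value} and the
#'   per-group means \code{mean_RD}, \code{mean_NR}, \code{mean_PR}.
#' @examples
#' sim <- imputeMissing(simulateCohort(nFeatures = 30, seed = 1), seed = 2)
#' head(anovaScan(sim))
#' @export
anovaScan <- function(x, labels = responseLabels(x), log2 = FALSE) {
  m <- if (methods::is(x, "BiomarkerExperiment")) abundance(x) else as.matrix(x)
  if (anyNA(m))
    stop("matrix contains missing values; impute first (imputeMissing)")
  labels <- droplevels(factor(labels))
  if (length(labels) != ncol(m))
    stop("need one label per sample")
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("at least two response groups are required")
  if (any(counts < 2L))
    stop("every group needs at least 2 samples (violated by: ",
         paste(names(counts)[counts < 2L], collapse = ", "), ")")
  if (log2) m <- base::log2(m)

  k <- length(counts); n <- ncol(m)
  groupIdx <- split(seq_len(n), labels)
  gm <- vapply(groupIdx, function(j) rowMeans(m[, j, drop = FALSE]),
               numeric(nrow(m)))
  gm <- matrix(gm, nrow = nrow(m))   # features x groups
  grand <- rowMeans(m)
  ng <- as.numeric(counts)
  ssb <- as.numeric((gm - grand)^2 %*% ng)
  ssw <- numeric(nrow(m))
  for (g in seq_len(k)) {
    j <- groupIdx[[g]]
    ssw <- ssw + rowSums((m[, j, drop = FALSE] - gm[, g])^2)
  }
  df1 <- k - 1L; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # zero within-group variance conventions (scale-relative tolerance)
  tol <- 1e-12 * pmax(1, rowMeans(m^2))
  degenerate <- ssw <= tol
  sig <- degenerate & ssb > tol
  flat <- degenerate & ssb <= tol
  f[sig] <- Inf; p[sig] <- 0
  f[flat] <- 0;  p[flat] <- 1
  out <- data.frame(feature_id = rownames(m), f_statistic = f, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cls in responseClasses())
    out[[paste0("mean_", cls)]] <-
      if (cls %in% names(groupIdx)) gm[, match(cls, names(groupIdx))]
      else NA_real_
  out
}

#' Filter differentially expressed features
#'
#' Retains features with p-value strictly below \code{alpha}, preserving
#' input order. No multiple-testing correction is applied by default; a
#' Benjamini-Hochberg option is available.
#'
#' @param results data.frame from \code{\link{anovaScan}}.
#' @param alpha significance threshold in (0, 1]; \code{alpha = 1} is the
#'   vacuous filter (every feature with p < 1 passes).
#' @param method \code{"none"} (raw p, the default) or \code{"BH"}.
#' @return Character vector of feature IDs passing the filter.
#' @export
filterDeps <- function(results, alpha = 0.05, method = c("none", "BH")) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  method <- match.arg(method)
  p <- results$p_value
  if (method == "BH") p <- stats::p.adjust(p, method = "BH")
  results$feature_id[p < alpha]
}
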