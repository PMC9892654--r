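# Group-mean shift patterns (RD, NR, PR multipliers of effectSize*noiseSd)
# assigned cyclically to informative features so that both directions of
# differential expression occur, as seen in real marker heatmaps.
shiftPatterns <- list(
  rd_high   = c(1, 0, 0),
  pr_high   = c(0, 0, 1),
  nr_high   = c(0, 1, 0),
  rd_low    = c(-1, 0, 0),
  pr_low    = c(0, 0, -1),
  monotone  = c(1, 0, -1))

#' Simulate a pharmacoproteomic cohort with planted biomarkers
#'
#' Generates a features x samples abundance matrix with three response
#' groups and a known set of group-discriminative ("informative")
#' features, for validating the discovery pipeline against ground truth.
#' Log-scale abundances are Normal: every feature gets a baseline mean
#' (Normal(10, 1)); informative features additionally receive a
#' group-specific mean shift of magnitude \code{effectSize * noiseSd},
#' with shift patterns (e.g. RD-high, PR-low, monotone RD>NR>PR) assigned
#' cyclically so both directions of differential expression occur.
#' Non-informative features are pure noise. Cells are then masked missing
#' independently at rate \code{missingFraction}.
#'
#' Defaults mirror a 40-sample discovery cohort with group sizes 14/17/9
#' and a 0.16\% missingness rate.
#'
#' @param nFeatures total number of features.
#' @param nSamples total number of samples.
#' @param groupSizes integer vector (RD, NR, PR) summing to
#'   \code{nSamples}.
#' @param nInformative number of planted discriminative features
#'   (<= \code{nFeatures}).
#' @param effectSize between-group mean shift in units of within-group SD.
#' @param noiseSd within-group standard deviation.
#' @param missingFraction fraction of cells masked missing, in [0, 1).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @return A \linkS4class{BiomarkerExperiment} with response labels in
#'   \code{colData} and the planted feature IDs retrievable via
#'   \code{\link{informativeFeatures}}.
#' @examples
#' sim <- simulateCohort(nFeatures = 50, seed = 1)
#' table(responseLabels(sim))
#' head(informativeFeatures(sim))
#' @export
simulateCohort <- function(nFeatures = 100L, nSamples = 40L,
                           groupSizes = c(RD = 14L, NR = 17L, PR = 9L),
                           nInformative = 10L, effectSize = 3,
                           noiseSd = 1, missingFraction = 0.0016,
                           seed) {
  if (length(groupSizes) != 3L)
    stop("groupSizes must give counts for the three classes (RD, NR, PR)")
  if (sum(groupSizes) != nSamples)
    stop("groupSizes must sum to nSamples")
  if (nInformative > nFeatures)
    stop("nInformative must not exceed nFeatures")
  if (missingFraction < 0 || missingFraction >= 1)
    stop("missingFraction must lie in [0, 1)")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  if (missing(seed)) stop("an integer seed is required")

  featureIds <- sprintf("P%04d", seq_len(nFeatures))
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  groups <- factor(rep(responseClasses(), times = groupSizes),
                   levels = responseClasses())

  withSeed(seed, {
    informative <- sort(sample.int(nFeatures, nInformative))
    baseline <- rnorm(nFeatures, mean = 10, sd = 1)
    vals <- matrix(rnorm(nFeatures * nSamples, sd = noiseSd),
                   nFeatures, nSamples) + baseline
    for (k in seq_along(informative)) {
      pat <- shiftPatterns[[(k - 1L) %% length(shiftPatterns) + 1L]]
      shift <- pat[as.integer(groups)] * effectSize * noiseSd
      vals[informative[k], ] <- vals[informative[k], ] + shift
    }
    if (missingFraction > 0) {
      mask <- runif(length(vals)) < missingFraction
      vals[mask] <- NA_real_
    }
    dimnames(vals) <- list(featureIds, sampleIds)
    BiomarkerExperiment(vals, response = groups,
                        metadata = list(informative = featureIds[informative]))
  })
}
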