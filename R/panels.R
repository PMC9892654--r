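#' Enumerate all feature panels of a given size
#'
#' All \code{choose(length(pool), size)} subsets of the pool, in
#' lexicographic order with respect to the pool's own ordering.
#'
#' @param pool character vector of feature IDs.
#' @param size panel size, between 1 and \code{length(pool)}.
#' @return Character matrix with one panel per column (\code{size} rows).
#' @examples
#' ncol(enumeratePanels(letters[1:16], 2))  # 120
#' @export
enumeratePanels <- function(pool, size) {
  size <- as.integer(size)
  if (size < 1L || size > length(pool))
    stop("size must lie between 1 and the pool size (", length(pool), ")")
  combn(pool, size)
}

#' Exhaustive evaluation of all panels at the requested sizes
#'
#' Evaluates every subset of the pool at each requested size with
#' \code{\link{evaluateFeatures}} under one shared holdout plan, and
#' reports the best panel per size (ties broken lexicographically, i.e.
#' the first panel in enumeration order wins).
#'
#' @param x a fully imputed \linkS4class{BiomarkerExperiment}.
#' @param pool character vector of candidate feature IDs.
#' @param sizes integer vector of panel sizes to enumerate.
#' @param plan a \linkS4class{HoldoutPlan} shared by every evaluation.
#' @param labels optional response factor; defaults to
#'   \code{responseLabels(x)}.
#' @param cap guard on the total number of panels across sizes
#'   (default 1e5); exceeding it is an error suggesting to reduce sizes
#'   or raise the cap.
#' @return List with \code{evaluations} (data.frame: size, panel
#'   (comma-joined IDs), mean_accuracy, accuracy_sd) and \code{best}
#'   (data.frame with the arg-max panel per size).
#' @export
panelSearch <- function(x, pool, sizes, plan, labels = responseLabels(x),
                        cap = 1e5) {
  sizes <- as.integer(sizes)
  total <- sum(choose(length(pool), sizes))
  if (total > cap)
    stop("exhaustive search over ", total, " panels exceeds the cap (",
         format(cap, scientific = FALSE),
         "); reduce the sizes or raise 'cap'")
  evalRows <- vector("list", length(sizes))
  bestRows <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    panels <- enumeratePanels(pool, sizes[k])
    stats <- apply(panels, 2, function(p) {
      r <- replicateAccuracies(
        evaluateFeatures(x, p, plan, labels, computeAuc = FALSE))
      c(mean(r), sd(r))
    })
    df <- data.frame(size = sizes[k],
                     panel = apply(panels, 2, paste, collapse = ","),
                     mean_accuracy = stats[1L, ],
                     accuracy_sd = stats[2L, ],
                     stringsAsFactors = FALSE)
    evalRows[[k]] <- df
    bestRows[[k]] <- df[which.max(df$mean_accuracy), , drop = FALSE]
  }
  list(evaluations = do.call(rbind, c(evalRows, make.row.names = FALSE)),
       best = do.call(rbind, c(bestRows, make.row.names = FALSE)))
}
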