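# Internal implicant representation: integers (value, mask) where a set
# mask bit marks a specified variable and value holds its required bit.
# Variable 1 maps to the most significant bit, so the bit-vector (A,B,C)
# = (0,0,1) is minterm 1.

bitsToInt <- function(bits) {
  n <- length(bits)
  sum(as.integer(bits) * 2^((n - 1L):0L))
}

implicantToRow <- function(value, mask, nVars) {
  vapply(seq_len(nVars), function(j) {
    b <- 2^(nVars - j)
    if (bitwAnd(mask, b) == 0) NA_integer_
    else as.integer(bitwAnd(value, b) != 0)
  }, integer(1))
}

termKey <- function(row) {
  paste(ifelse(is.na(row), "-", as.character(row)), collapse = "")
}

covers <- function(value, mask, minterm) bitwAnd(minterm, mask) == value

newSop <- function(termRows, nVars) {
  t <- if (length(termRows) == 0L)
    matrix(integer(), 0L, nVars)
  else do.call(rbind, termRows)
  keys <- apply(t, 1L, termKey)
  t <- t[order(keys), , drop = FALSE]
  storage.mode(t) <- "integer"
  methods::new("SopFunction", nVars = as.integer(nVars), terms = t)
}

#' Build a sum-of-products function from explicit terms
#'
#' @param terms integer matrix over \{0, 1, NA\} with one product term
#'   per row and one column per variable (NA = don't-care). A zero-row
#'   matrix gives the constant-0 function.
#' @param nVars number of variables (defaults to \code{ncol(terms)}).
#' @return A \linkS4class{SopFunction}.
#' @examples
#' f <- sopFunction(rbind(c(0, NA, 1), c(1, 1, NA)))  # A'C + AB
#' evaluateSop(f, c(0, 1, 1))
#' @export
sopFunction <- function(terms, nVars = ncol(terms)) {
  terms <- as.matrix(terms)
  storage.mode(terms) <- "integer"
  newSop(lapply(seq_len(nrow(terms)), function(i) terms[i, ]), nVars)
}

#' @export
#' @rdname sopTerms
#' @aliases sopTerms,SopFunction-method
#' @param x a \linkS4class{SopFunction}.
setMethod("sopTerms", "SopFunction", function(x) x@terms)

#' Number of variables of a Boolean function
#'
#' @param x a \linkS4class{SopFunction}.
#' @return Integer.
#' @export
#' @aliases nVariables,SopFunction-method
#' @rdname nVariables
setMethod("nVariables", "SopFunction", function(x) x@nVars)

#' Evaluate a sum-of-products function on one assignment
#'
#' OR over the function's product terms of the AND over their specified
#' literals; don't-care positions are always satisfied.
#'
#' @param f a \linkS4class{SopFunction}.
#' @param assignment binary vector of length \code{nVariables(f)}.
#' @return 0 or 1.
#' @export
evaluateSop <- function(f, assignment) {
  if (length(assignment) != f@nVars)
    stop("assignment length ", length(assignment),
         " does not match nVars = ", f@nVars)
  if (nrow(f@terms) == 0L) return(0L)
  for (i in seq_len(nrow(f@terms))) {
    t <- f@terms[i, ]
    spec <- !is.na(t)
    if (all(t[spec] == assignment[spec])) return(1L)
  }
  0L
}

#' Exact Boolean minimization (Quine-McCluskey + Petrick)
#'
#' Computes a minimum two-level sum-of-products cover of the Boolean
#' function defined by a set of minterms: prime implicants are generated
#' by iterated pairwise merging (the Quine-McCluskey tabulation), the
#' essential primes are taken first, and any residual cyclic core is
#' resolved exactly by exhaustive search over prime subsets (Petrick's
#' method). Among minimum-cardinality covers the one with fewest total
#' literals is chosen, with remaining ties broken lexicographically on
#' the term patterns, so the answer is deterministic and unique.
#'
#' @param minterms the ON-set: either a 0/1 matrix with one minterm per
#'   row and \code{nVars} columns, or an integer vector of distinct
#'   minterm indices in [0, 2^nVars).
#' @param nVars number of variables (<= 20; required when `minterms` is
#'   an index vector, inferred from the matrix otherwise).
#' @return A \linkS4class{SopFunction} that is logically equivalent to
#'   the minterm set, consists only of prime implicants, and has minimum
#'   term count (and, among those, minimum literal count). The empty set
#'   gives the constant-0 function; the full set the constant-1 function
#'   (one all-don't-care term).
#' @examples
#' m <- rbind(c(0,0,1), c(0,1,1), c(1,1,0), c(1,1,1))
#' sopTerms(minimizeBoolean(m))        # A'C + AB
#' @export
minimizeBoolean <- function(minterms, nVars = NULL) {
  if (is.matrix(minterms) || is.data.frame(minterms)) {
    minterms <- as.matrix(minterms)
    if (is.null(nVars)) nVars <- ncol(minterms)
    if (ncol(minterms) != nVars)
      stop("minterm matrix must have nVars columns")
    vals <- minterms[!is.na(minterms)]
    if (length(vals) != length(minterms) || !all(vals %in% c(0, 1)))
      stop("minterms must be fully specified binary vectors")
    idx <- apply(minterms, 1L, bitsToInt)
  } else {
    if (is.null(nVars)) stop("nVars is required for minterm indices")
    idx <- as.integer(minterms)
  }
  nVars <- as.integer(nVars)
  if (nVars < 1L || nVars > 20L)
    stop("nVars must lie between 1 and 20")
  if (length(idx) && (any(idx < 0) || any(idx >= 2^nVars)))
    stop("minterm index out of range for ", nVars, " variables")
  if (anyDuplicated(idx))
    stop("minterms must be distinct")
  if (length(idx) == 0L)
    return(newSop(list(), nVars))

  primes <- primeImplicants(idx, nVars)
  cover <- selectCover(primes, idx, nVars)
  newSop(lapply(cover, function(p)
    implicantToRow(p$value, p$mask, nVars)), nVars)
}

# Quine-McCluskey tabulation: repeatedly merge implicant pairs that share
# a mask and differ in exactly one specified bit; unmerged implicants are
# prime.
primeImplicants <- function(idx, nVars) {
  fullMask <- as.integer(2^nVars - 1L)
  current <- unique(data.frame(value = as.integer(idx), mask = fullMask))
  primes <- list()
  repeat {
    m <- nrow(current)
    combined <- logical(m)
    nxt <- list()
    byMask <- split(seq_len(m), current$mask)
    for (grp in byMask) {
      if (length(grp) < 2L) next
      vals <- current$value[grp]
      mask <- current$mask[grp[1L]]
      for (a in seq_along(grp)) {
        diffs <- bitwXor(vals[a], vals)
        mates <- which(diffs > 0 & bitwAnd(diffs, diffs - 1L) == 0L)
        for (b in mates) {
          combined[grp[a]] <- TRUE
          combined[grp[b]] <- TRUE
          if (vals[a] < vals[b]) {
            bit <- bitwXor(vals[a], vals[b])
            nxt[[length(nxt) + 1L]] <-
              c(value = bitwAnd(vals[a], bitwNot(bit)),
                mask = bitwAnd(mask, bitwNot(bit)))
          }
        }
      }
    }
    for (i in which(!combined))
      primes[[length(primes) + 1L]] <-
        list(value = current$value[i], mask = current$mask[i])
    if (length(nxt) == 0L) break
    nxtDf <- unique(as.data.frame(do.call(rbind, nxt)))
    current <- nxtDf
  }
  primes
}

nLiterals <- function(p) sum(bitwAnd(p$mask, 2^(0:30)) > 0)

# Essential-prime extraction followed by exact resolution of the cyclic
# core (Petrick's problem) via branch-and-bound on the residual cover
# chart: all minimum-cardinality covers are enumerated, then ties are
# broken by total literal count and finally by the lexicographic order
# of the cover's term patterns, giving a deterministic unique answer.
selectCover <- function(primes, idx, nVars) {
  chart <- vapply(primes, function(p)
    covers(p$value, p$mask, as.integer(idx)), logical(length(idx)))
  chart <- matrix(chart, nrow = length(idx))
  coverCount <- rowSums(chart)
  chosen <- sort(unique(unlist(lapply(which(coverCount == 1L),
                                      function(r) which(chart[r, ])))))
  uncovered <- which(!apply(chart[, chosen, drop = FALSE], 1L, any))
  if (length(uncovered)) {
    rest <- which(colSums(chart[uncovered, , drop = FALSE]) > 0)
    rest <- setdiff(rest, chosen)
    sub <- chart[uncovered, rest, drop = FALSE]
    best <- length(rest) + 1L
    minimal <- list()
    recurse <- function(rows, sel) {
      if (length(rows) == 0L) {
        k <- length(sel)
        if (k < best) { best <<- k; minimal <<- list() }
        if (k == best) minimal[[length(minimal) + 1L]] <<- sort(sel)
        return(invisible())
      }
      if (length(sel) + 1L > best) return(invisible())
      r <- rows[which.min(rowSums(sub[rows, , drop = FALSE]))]
      for (p in which(sub[r, ]))
        recurse(rows[!sub[rows, p]], c(sel, p))
      invisible()
    }
    recurse(seq_along(uncovered), integer())
    minimal <- unique(minimal)
    found <- lapply(minimal, function(s) rest[s])
    lits <- vapply(found, function(s)
      sum(vapply(primes[s], nLiterals, numeric(1))), numeric(1))
    found <- found[lits == min(lits)]
    if (length(found) > 1L) {
      keys <- vapply(found, function(s)
        paste(sort(vapply(primes[s], function(p)
          termKey(implicantToRow(p$value, p$mask, nVars)),
          character(1))), collapse = "|"), character(1))
      found <- found[order(keys)]
    }
    chosen <- sort(c(chosen, found[[1L]]))
  }
  primes[chosen]
}

#' Render a product term in prime notation
#'
#' Formats one term row as e.g. \code{A'C} (single-letter variables) or
#' \code{AQP1'·VPS25}: a trailing prime marks a complemented (low)
#' literal, don't-care variables are omitted, and multi-character names
#' are joined with a middle dot.
#'
#' @param term integer vector over \{0, 1, NA\}.
#' @param varNames variable names, one per position (default A, B, C...).
#' @param sep separator; by default empty for single-letter names and
#'   a middle dot otherwise.
#' @return Character scalar; the all-don't-care term renders as "1" and
#'   is the constant-1 term.
#' @examples
#' formatTerm(c(0, NA, 1))                         # "A'C"
#' formatTerm(c(0, 1), c("AQP1", "VPS25"))         # "AQP1'·VPS25"
#' @export
formatTerm <- function(term, varNames = LETTERS[seq_along(term)],
                       sep = NULL) {
  spec <- which(!is.na(term))
  if (length(spec) == 0L) return("1")
  if (is.null(sep))
    sep <- if (all(nchar(varNames[spec]) == 1L)) "" else "·"
  lits <- paste0(varNames[spec], ifelse(term[spec] == 0L, "'", ""))
  paste(lits, collapse = sep)
}

#' Render a sum-of-products function
#'
#' @param f a \linkS4class{SopFunction}.
#' @param varNames variable names (default A, B, C...).
#' @return Character scalar such as \code{"A'C + AB"}; the constant-0
#'   function renders as \code{"0"}.
#' @export
formatSop <- function(f, varNames = LETTERS[seq_len(f@nVars)]) {
  if (nrow(f@terms) == 0L) return("0")
  paste(apply(f@terms, 1L, formatTerm, varNames = varNames),
        collapse = " + ")
}

setMethod("show", "SopFunction", function(object) {
  cat("SopFunction over", object@nVars, "variables,",
      nrow(object@terms), "terms:", formatSop(object), "\n")
})
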