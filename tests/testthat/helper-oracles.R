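# Independent oracles used across the suite. These deliberately take the
# brute-force route (explicit enumeration, stats::oneway.test) so they
# share no code with the implementation they check.

# All 2^n assignments over n variables, one per row, variable 1 = MSB.
allAssignments <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n))[, n:1, drop = FALSE])
  dimnames(m) <- NULL
  m
}

# Truth table (length 2^n, ordered by minterm index) of an SOP function,
# evaluated through the package's single-assignment evaluator.
truthTable <- function(f) {
  asg <- allAssignments(nVariables(f))
  vapply(seq_len(nrow(asg)), function(i) evaluateSop(f, asg[i, ]),
         integer(1))
}

# Truth table of a raw minterm matrix (membership test).
mintermTable <- function(minterms, n) {
  idx <- apply(minterms, 1L, function(b) sum(b * 2^((n - 1):0))) + 1L
  tt <- integer(2^n)
  tt[idx] <- 1L
  tt
}

# A term (vector over {0,1,NA}) covers an assignment iff all specified
# literals agree.
termCoversAssignment <- function(term, asg) {
  s <- !is.na(term)
  all(term[s] == asg[s])
}

# Brute-force prime implicants: enumerate all 3^n candidate terms, keep
# implicants (every covered assignment is in the ON-set), keep those that
# stay implicants under no single-literal widening.
bruteForcePrimes <- function(onSet, n) {
  asg <- allAssignments(n)
  on <- mintermTable(onSet, n) == 1L
  cands <- as.matrix(expand.grid(rep(list(c(0L, 1L, NA)), n)))
  dimnames(cands) <- NULL
  isImplicant <- function(term) {
    cov <- vapply(seq_len(nrow(asg)), function(i)
      termCoversAssignment(term, asg[i, ]), logical(1))
    any(cov) && all(on[cov])
  }
  imps <- cands[vapply(seq_len(nrow(cands)), function(i)
    isImplicant(cands[i, ]), logical(1)), , drop = FALSE]
  prime <- vapply(seq_len(nrow(imps)), function(i) {
    t <- imps[i, ]
    for (j in which(!is.na(t))) {
      w <- t; w[j] <- NA
      if (isImplicant(w)) return(FALSE)
    }
    TRUE
  }, logical(1))
  imps[prime, , drop = FALSE]
}

# Exact minimum set-cover cardinality by branching on the least-covered
# minterm (exhaustive over prime subsets, with pruning).
minCoverSize <- function(chart) {
  if (nrow(chart) == 0L) return(0L)
  best <- Inf
  recurse <- function(rows, depth) {
    if (depth >= best) return()
    if (length(rows) == 0L) { best <<- depth; return() }
    counts <- rowSums(chart[rows, , drop = FALSE])
    r <- rows[which.min(counts)]
    for (p in which(chart[r, ])) {
      left <- rows[!chart[rows, p]]
      recurse(left, depth + 1L)
    }
  }
  recurse(seq_len(nrow(chart)), 0L)
  best
}

# Minimum number of prime-implicant terms needed to cover an ON-set,
# computed entirely with the brute-force machinery above.
oracleMinCover <- function(onSet, n) {
  primes <- bruteForcePrimes(onSet, n)
  chart <- vapply(seq_len(nrow(primes)), function(p)
    vapply(seq_len(nrow(onSet)), function(r)
      termCoversAssignment(primes[p, ], onSet[r, ]), logical(1)),
    logical(nrow(onSet)))
  chart <- matrix(chart, nrow = nrow(onSet))
  minCoverSize(chart)
}

# Random ON-set over n variables with the given density; at least one
# minterm.
randomOnSet <- function(n, density = 0.4) {
  keep <- which(runif(2^n) < density)
  if (length(keep) == 0L) keep <- sample.int(2^n, 1L)
  asg <- allAssignments(n)
  asg[keep, , drop = FALSE]
}

# Small imputed cohort shared by classifier-level tests.
makeCohort <- function(seed, nFeatures = 100L, effectSize = 3, ...) {
  imputeMissing(simulateCohort(nFeatures = nFeatures,
                               effectSize = effectSize, seed = seed, ...),
                seed = seed + 1000L)
}
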