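binFromBits <- function(bitsMat, scheme = list(type = "median")) {
  methods::new("BinarizedMatrix", bits = bitsMat, scheme = scheme)
}

toyLabels <- function(counts) {
  factor(rep(responseClasses(), times = counts), levels = responseClasses())
}

test_that("median binarization divides by the feature median and thresholds", {
  m <- rbind(P1 = c(1, 2, 8, 9))
  colnames(m) <- paste0("S", 1:4)
  expect_identical(unname(bits(binarize(m))[1, ]), c(0L, 0L, 1L, 1L))
  # scale invariance: any positive rescaling keeps the same bits
  for (c in c(0.01, 3, 1e4))
    expect_identical(bits(binarize(m * c)), bits(binarize(m)))
  # log transform preserves the median ordering, hence the bits
  expect_identical(bits(binarize(log(m + 1))), bits(binarize(m)))
  # a value exactly at the median maps low by default, high on request
  m2 <- rbind(P1 = c(1, 2, 3, 4, 5))
  colnames(m2) <- paste0("S", 1:5)
  expect_identical(unname(bits(binarize(m2))[1, ]),
                   c(0L, 0L, 0L, 1L, 1L))
  expect_identical(unname(bits(binarize(m2, tieHigh = TRUE))[1, ]),
                   c(0L, 0L, 1L, 1L, 1L))
  bad <- rbind(P1 = c(-2, -1, 0, 1))
  colnames(bad) <- paste0("S", 1:4)
  expect_error(binarize(bad), "non-positive median for feature 'P1'")
})

test_that("quantile-band binarization leaves the middle indeterminate", {
  m <- rbind(P1 = 1:10)
  colnames(m) <- paste0("S", 1:10)
  b <- bits(binarize(m, quantileBand(0.3, 0.7)))[1, ]
  q <- quantile(1:10, c(0.3, 0.7))   # 3.7 and 7.3
  expect_identical(unname(b[m[1, ] < q[1]]), rep(0L, 3))
  expect_identical(unname(b[m[1, ] > q[2]]), rep(1L, 3))
  expect_true(all(is.na(b[4:7])))
  expect_error(quantileBand(0.7, 0.3), "low < high")
})

test_that("group truth tables collect distinct patterns with frequencies", {
  bitsMat <- rbind(A = c(0, 0, 1, 1, 1),
                   B = c(0, 1, 1, 1, 1),
                   C = c(1, 1, 0, 1, 1))
  colnames(bitsMat) <- paste0("S", 1:5)
  storage.mode(bitsMat) <- "integer"
  labels <- toyLabels(c(5, 0, 0))
  tt <- groupTruthTable(binFromBits(bitsMat), labels, "RD")
  expect_identical(nrow(tt$minterms), 4L)   # 001, 011, 110, 111
  expect_identical(tt$counts, c(1L, 1L, 1L, 2L))
  expect_equal(sum(tt$frequencies), 1)
  expect_error(groupTruthTable(binFromBits(bitsMat), labels, "PR"),
               "no samples")
  # identical samples collapse to a single full-frequency minterm
  same <- binFromBits(matrix(1L, 3, 4,
    dimnames = list(c("A", "B", "C"), paste0("S", 1:4))))
  tt2 <- groupTruthTable(same, toyLabels(c(4, 0, 0)), "RD")
  expect_identical(nrow(tt2$minterms), 1L)
  expect_equal(tt2$frequencies, 1)
})

test_that("the worked truth table yields the two-signature cover", {
  bitsMat <- rbind(A = c(0, 0, 1, 1),
                   B = c(0, 1, 1, 1),
                   C = c(1, 1, 0, 1))
  colnames(bitsMat) <- paste0("S", 1:4)
  storage.mode(bitsMat) <- "integer"
  sigs <- deriveSignatures(binFromBits(bitsMat), toyLabels(c(4, 0, 0)))
  expect_named(sigs, "RD")
  ss <- sigs$RD
  expect_identical(signatureTerms(ss),
                   rbind(c(0L, NA, 1L), c(1L, 1L, NA)))   # A'C, AB
  # A'C covers samples 1,2; AB covers samples 3,4
  expect_equal(unname(signatureCoverage(ss)), c(0.5, 0.5))
  expect_identical(signatureGroup(ss), "RD")
})

test_that("a group exhausting all patterns collapses to the tautology", {
  asg <- t(allAssignments(2))
  rownames(asg) <- c("A", "B"); colnames(asg) <- paste0("S", 1:4)
  storage.mode(asg) <- "integer"
  sigs <- deriveSignatures(binFromBits(asg), toyLabels(c(4, 0, 0)))
  expect_identical(signatureTerms(sigs$RD), matrix(NA_integer_, 1, 2))
  expect_equal(unname(signatureCoverage(sigs$RD)), 1)
})

test_that("signature matching uses consistent-with semantics", {
  term <- c(0L, NA, 1L)                       # A'C
  expect_true(matchTerm(c(0, 1, 1), term))
  expect_false(matchTerm(c(1, 1, 1), term))   # A literal violated
  expect_true(matchTerm(c(NA, 0, 1), term))   # indeterminate A passes
  expect_false(matchTerm(c(0, NA, 0), term))
  expect_error(matchTerm(c(0, 1), term), "lengths")
})

test_that("every discovery sample matches its own group's signatures", {
  # joint-coverage invariant, checked across random synthetic cohorts
  for (s in 1:25) {
    sim <- makeCohort(400 + s, nFeatures = 20, nInformative = 5)
    panel <- informativeFeatures(sim)
    b <- binarize(sim[panel, ])
    labels <- responseLabels(sim)
    sigs <- suppressWarnings(deriveSignatures(b, labels))
    pred <- predictResponse(b, sigs)
    own <- mapply(function(p, g) g %in% strsplit(p, ",")[[1]],
                  pred$predicted, as.character(labels))
    expect_true(all(own))
  }
})

test_that("signatures of one group ignore the other groups' samples", {
  sim <- makeCohort(431, nFeatures = 12, nInformative = 4)
  panel <- informativeFeatures(sim)
  labels <- responseLabels(sim)
  b <- binarize(sim[panel, ])
  sigsA <- suppressWarnings(deriveSignatures(b, labels))
  # permute the NR samples' columns; RD and PR signatures must not move
  idx <- seq_along(labels)
  nr <- which(labels == "NR")
  set.seed(1); idx[nr] <- sample(nr)
  b2 <- binFromBits(bits(b)[, idx])
  sigsB <- suppressWarnings(deriveSignatures(b2, labels[idx]))
  expect_identical(signatureTerms(sigsA$RD), signatureTerms(sigsB$RD))
  expect_identical(signatureTerms(sigsA$PR), signatureTerms(sigsB$PR))
})

test_that("prediction reports no-calls and multi-group matches as-is", {
  rd <- methods::new("SignatureSet", group = "RD",
                     variables = c("A", "B"),
                     terms = rbind(c(1L, 1L)), coverage = 1)
  nr <- methods::new("SignatureSet", group = "NR",
                     variables = c("A", "B"),
                     terms = rbind(c(1L, NA)), coverage = 1)
  pr <- methods::new("SignatureSet", group = "PR",
                     variables = c("A", "B"),
                     terms = rbind(c(0L, 0L)), coverage = 1)
  sigs <- list(RD = rd, NR = nr, PR = pr)
  bitsMat <- matrix(c(1L, 1L,   # matches RD and NR
                      1L, 0L,   # matches NR only
                      0L, 1L),  # matches nothing
                    nrow = 2,
                    dimnames = list(c("A", "B"), paste0("S", 1:3)))
  pred <- predictResponse(binFromBits(bitsMat), sigs)
  expect_identical(pred$predicted, c("RD,NR", "NR", ""))
  expect_identical(pred$n_groups, c(2L, 1L, 0L))
  expect_identical(pred$matched[[1]]$RD, 1L)
})

test_that("signature sets survive a JSON round trip", {
  sim <- makeCohort(440, nFeatures = 15, nInformative = 5)
  b <- binarize(sim[informativeFeatures(sim), ])
  sigs <- suppressWarnings(deriveSignatures(b, responseLabels(sim)))
  path <- withr::local_tempfile(fileext = ".json")
  writeSignatures(sigs, path, scheme = binarizationScheme(b))
  back <- readSignatures(path)
  expect_identical(names(back), names(sigs))
  for (g in names(sigs)) {
    expect_identical(signatureTerms(back[[g]]),
                     unname(signatureTerms(sigs[[g]])))
    expect_equal(signatureCoverage(back[[g]]), signatureCoverage(sigs[[g]]))
    expect_identical(back[[g]]@variables, sigs[[g]]@variables)
  }
  expect_identical(attr(back, "scheme")$type, "median")
})

test_that("cross-group pattern collisions warn but still derive", {
  bitsMat <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), nrow = 1,
                    dimnames = list("A", paste0("S", 1:6)))
  labels <- toyLabels(c(2, 2, 2))
  expect_warning(deriveSignatures(binFromBits(bitsMat), labels),
                 "observed in both RD and NR")
})
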