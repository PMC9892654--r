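test_that("row-wise F statistics match stats::oneway.test exactly", {
  set.seed(5)
  labels <- factor(rep(c("RD", "NR", "PR"), times = c(6, 7, 5)),
                   levels = responseClasses())
  m <- matrix(rnorm(50 * 18, mean = 10), 50, 18,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:18)))
  res <- anovaScan(BiomarkerExperiment(m, response = labels))
  for (i in seq_len(nrow(m))) {
    ref <- stats::oneway.test(m[i, ] ~ labels, var.equal = TRUE)
    expect_equal(res$f_statistic[i], unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(res$p_value[i], unname(ref$p.value), tolerance = 1e-10)
  }
  # group means are reported per class
  expect_equal(res$mean_RD[1], mean(m[1, labels == "RD"]))
})

test_that("degenerate features follow the documented conventions", {
  labels <- factor(rep(c("RD", "NR", "PR"), each = 3),
                   levels = responseClasses())
  flat <- rbind(P1 = rep(5, 9))
  colnames(flat) <- paste0("S", 1:9)
  resFlat <- anovaScan(BiomarkerExperiment(flat, response = labels))
  expect_equal(resFlat$p_value, 1)
  expect_equal(resFlat$f_statistic, 0)

  sep <- rbind(P1 = rep(c(0, 5, 10), each = 3))
  colnames(sep) <- paste0("S", 1:9)
  resSep <- anovaScan(BiomarkerExperiment(sep, response = labels))
  expect_equal(resSep$p_value, 0)
  expect_true(is.infinite(resSep$f_statistic))
})

test_that("well-separated group means give vanishing p-values", {
  set.seed(9)
  labels <- factor(rep(responseClasses(), each = 5),
                   levels = responseClasses())
  m <- rbind(P1 = rep(c(0, 5, 10), each = 5) + rnorm(15, sd = 0.1))
  colnames(m) <- paste0("S", 1:15)
  res <- anovaScan(BiomarkerExperiment(m, response = labels))
  expect_lt(res$p_value, 1e-6)
  ref <- stats::oneway.test(m[1, ] ~ labels, var.equal = TRUE)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("the scan is invariant to permuting samples within groups", {
  sim <- makeCohort(41, nFeatures = 30)
  labels <- responseLabels(sim)
  res <- anovaScan(sim)
  perm <- unlist(lapply(split(seq_along(labels), labels), sample),
                 use.names = FALSE)
  res2 <- anovaScan(BiomarkerExperiment(abundance(sim)[, perm],
                                        response = labels[perm]))
  expect_equal(res$f_statistic, res2$f_statistic, tolerance = 1e-12)
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-12)
})

test_that("preconditions are enforced", {
  labels <- factor(c("RD", "RD", "NR"), levels = responseClasses())
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("P1", "P2"), c("S1", "S2", "S3")))
  expect_error(anovaScan(BiomarkerExperiment(m, response = labels)),
               "at least 2 samples")
  m2 <- m; m2[1, 1] <- NA
  ok <- factor(c("RD", "RD", "NR", "NR"), levels = responseClasses())
  m3 <- cbind(m2, S4 = c(1, 2))
  expect_error(anovaScan(BiomarkerExperiment(m3, response = ok)), "impute")
})

test_that("the DEP filter keeps p < alpha in input order", {
  res <- data.frame(feature_id = paste0("P", 1:5),
                    p_value = c(0.5, 0.01, 0.04, 0.05, 0.2))
  expect_identical(filterDeps(res), c("P2", "P3"))
  expect_identical(filterDeps(data.frame(feature_id = "P1", p_value = 0.5)),
                   character(0))
  # a vacuous threshold keeps everything
  expect_identical(filterDeps(res, alpha = 1), res$feature_id)
  expect_error(filterDeps(res, alpha = 0), "alpha")
  # BH correction is stricter than raw p
  expect_true(length(filterDeps(res, method = "BH")) <=
              length(filterDeps(res)))
})

test_that("under the null the DEP rate is within 3 sigma of alpha", {
  sim <- imputeMissing(simulateCohort(nFeatures = 200, effectSize = 0,
                                      seed = 77), seed = 78)
  frac <- length(filterDeps(anovaScan(sim))) / 200
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
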