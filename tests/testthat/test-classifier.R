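planSmall <- function(n = 10, seed = 7, ...) HoldoutPlan(n, seed = seed, ...)

test_that("holdout plans validate and stratified splits respect classes", {
  expect_error(HoldoutPlan(testFraction = 0), "testFraction")
  expect_error(HoldoutPlan(5, splitSeeds = c(1, 1, 2, 3, 4)), "distinct")
  labels <- factor(rep(responseClasses(), times = c(14, 17, 9)),
                   levels = responseClasses())
  plan <- planSmall(20)
  splits <- holdoutSplits(plan, labels)
  expect_length(splits, 20L)
  for (s in splits) {
    # 3 + 3 + 2 held out, at least two of each class left for training
    expect_identical(as.integer(table(labels[s])), c(3L, 3L, 2L))
    expect_true(all(table(labels[-s]) >= 2))
  }
  # deterministic given the plan
  expect_identical(splits, holdoutSplits(plan, labels))
})

test_that("perfectly separable planted data is classified at accuracy 1", {
  sim <- makeCohort(101, effectSize = 10)
  rep <- evaluateFeatures(sim, informativeFeatures(sim), planSmall())
  expect_equal(meanAccuracy(rep), 1.0)
  expect_equal(unname(classMetrics(rep)$auc), c(1, 1, 1))
  expect_true(all(diag(confusionMatrix(rep)) == rowSums(confusionMatrix(rep))))
})

test_that("an identical plan yields an identical report", {
  sim <- makeCohort(102)
  feats <- informativeFeatures(sim)[1:4]
  r1 <- evaluateFeatures(sim, feats, planSmall())
  r2 <- evaluateFeatures(sim, feats, planSmall())
  expect_identical(replicateAccuracies(r1), replicateAccuracies(r2))
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  expect_identical(reportPredictions(r1), reportPredictions(r2))
})

test_that("confusion totals and derived per-class metrics are consistent", {
  sim <- makeCohort(103)
  plan <- planSmall(15)
  rep <- evaluateFeatures(sim, informativeFeatures(sim)[1:5], plan)
  cm <- confusionMatrix(rep)
  expect_equal(sum(cm), 15 * 8)   # replicates x (3+3+2 held out)
  # every class appears in test sets the stratified number of times
  expect_equal(unname(rowSums(cm)), c(3, 3, 2) * 15)
  met <- classMetrics(rep)
  expect_equal(met$precision, unname(diag(cm) / colSums(cm)))
  expect_equal(met$sensitivity, unname(diag(cm) / rowSums(cm)))
  # micro-average identity: constant test size makes the replicate mean
  # equal the pooled accuracy
  expect_equal(meanAccuracy(rep), sum(diag(cm)) / sum(cm))
})

test_that("standardization uses training statistics only (no test leakage)", {
  sim <- makeCohort(104)
  feats <- informativeFeatures(sim)[1:5]
  plan <- HoldoutPlan(1, seed = 9)
  testIdx <- holdoutSplits(plan, responseLabels(sim))[[1]]
  r1 <- evaluateFeatures(sim, feats, plan)
  # corrupt ONE held-out sample's value of one panel feature
  a <- abundance(sim)
  a[feats[1], testIdx[1]] <- a[feats[1], testIdx[1]] * 1000 + 50
  sim2 <- BiomarkerExperiment(a, response = responseLabels(sim))
  r2 <- evaluateFeatures(sim2, feats, plan)
  p1 <- reportPredictions(r1); p2 <- reportPredictions(r2)
  untouched <- p1$sample_id != colnames(sim)[testIdx[1]]
  # training fit and standardization unchanged: all other test samples
  # keep identical predictions and decision scores
  expect_identical(p1[untouched, ], p2[untouched, ])
})

test_that("shuffled labels destroy accuracy relative to true labels", {
  sim <- makeCohort(105, effectSize = 5)
  feats <- informativeFeatures(sim)
  plan <- planSmall(15)
  trueAcc <- meanAccuracy(evaluateFeatures(sim, feats, plan))
  set.seed(6)
  shuffled <- sample(responseLabels(sim))
  nullAcc <- meanAccuracy(evaluateFeatures(sim, feats, plan,
                                           labels = shuffled))
  expect_gt(trueAcc, 0.9)
  expect_lt(nullAcc, 0.65)
  expect_gt(trueAcc - nullAcc, 0.25)
})

test_that("evaluation preconditions are enforced", {
  sim <- makeCohort(106)
  plan <- planSmall()
  expect_error(evaluateFeatures(sim, character(0), plan), "non-empty")
  expect_error(evaluateFeatures(sim, c("P0001", "NOPE"), plan),
               "unknown feature ID: NOPE")
  raw <- simulateCohort(missingFraction = 0.2, seed = 5)
  expect_error(evaluateFeatures(raw, "P0001", plan), "impute")
})

test_that("unstratified splits can lose a class, which is an error", {
  labels <- factor(rep(responseClasses(), times = c(6, 6, 2)),
                   levels = responseClasses())
  m <- matrix(rnorm(3 * 14, 10), 3, 14,
              dimnames = list(paste0("P", 1:3), paste0("S", 1:14)))
  be <- BiomarkerExperiment(m, response = labels)
  # seed chosen so that some replicate holds out both PR samples
  plan <- HoldoutPlan(50, testFraction = 0.3, stratified = FALSE, seed = 1)
  expect_error(evaluateFeatures(be, rownames(be), plan),
               "absent from the training split")
})

test_that("accuracy summaries are plain means over replicates", {
  mk <- function(acc) methods::new("EvalReport", features = "P1",
    perReplicateAccuracy = acc,
    confusion = matrix(0L, 3, 3), precision = numeric(3),
    sensitivity = numeric(3), auc = numeric(3),
    predictions = data.frame())
  expect_equal(accuracySummary(mk(rep(0.5, 10))), 0.5)
  expect_equal(accuracySummary(mk(c(0, 1))), 0.5)
  sim <- makeCohort(107)
  rep <- evaluateFeatures(sim, informativeFeatures(sim)[1:3], planSmall(5))
  expect_equal(accuracySummary(rep), mean(replicateAccuracies(rep)),
               tolerance = 1e-12)
})
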