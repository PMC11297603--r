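test_that("rank-based AUC handles separation, ties and mixed orderings", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  # 2 concordant + 2 discordant of the 4 positive-negative pairs
  expect_equal(rocAUC(c(0.8, 0.6, 0.7, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_error(rocAUC(c(0.1, 0.2), c(1, 1)), "one class")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(rocAUC(s, y), bruteForceAUC(s, y), tolerance = 1e-12)
  }
})

test_that("rank-based AUC agrees with an independent ROC library", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAUC(s, y), ref, tolerance = 1e-12)
  }
})

test_that("stratified splitting allocates per class and is deterministic", {
  X <- randomBits(100, 16, seed = 2)
  y <- c(rep(1L, 30), rep(0L, 70))
  tk <- taskDataset("t", paste0("c", 1:100), X, y)
  sp <- stratifiedSplit(tk, seed = 5)
  posTrain <- sum(taskLabels(sp) == 1 & splitTags(sp) == "train")
  expect_lte(abs(posTrain - 21), 1)           # 30 * 0.7
  expect_equal(sum(splitTags(sp) == "train"), 70)
  expect_equal(sum(splitTags(sp) == "validation"), 10)
  expect_equal(sum(splitTags(sp) == "test"), 20)
  sp2 <- stratifiedSplit(tk, seed = 5)
  expect_identical(splitTags(sp), splitTags(sp2))
  sp3 <- stratifiedSplit(tk, seed = 6)
  expect_false(identical(splitTags(sp), splitTags(sp3)))
  oneClass <- taskDataset("bad", paste0("c", 1:10), X[1:10, ], rep(1L, 10))
  expect_error(stratifiedSplit(oneClass), "one class")
})

test_that("layer inputs have width m, then m + T after stacking", {
  b <- makeTinyBenchmark(nTasks = 2L, n = 60L, m = 64L)
  l1 <- trainLayer(b$tasks, NULL, smallParams)
  expect_equal(unique(l1$inputWidths), 64L)
  S <- lapply(b$tasks, function(tk)
    scoreAll(l1, features(tk)))
  l2 <- trainLayer(b$tasks, S, smallParams)
  expect_equal(unique(l2$inputWidths), 64L + 2L)
  l2x <- trainLayer(b$tasks, S, smallParams, includeOwnScore = FALSE)
  expect_equal(unique(l2x$inputWidths), 64L + 1L)
  # coverage gap: scores missing rows
  Sbad <- lapply(S, function(s) s[-1, , drop = FALSE])
  expect_error(trainLayer(b$tasks, Sbad, smallParams), "cover")
})

test_that("layer scoring is deterministic, bounded and leaf-exact", {
  b <- makeTinyBenchmark(nTasks = 2L, n = 60L, m = 64L)
  l1 <- trainLayer(b$tasks, NULL, smallParams)
  X <- features(b$tasks[[1]])[rep(1, 5), ]
  S <- scoreAll(l1, X)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(apply(S, 2, function(col) all(col == col[1]))))
  expect_error(scoreAll(l1, X[, 1:10]), "width")
  # one tree on perfectly separable data: pure leaves give 0/1 scores
  Xs <- rbind(matrix(0, 10, 4), matrix(1, 10, 4))
  colnames(Xs) <- paste0("F", 1:4)
  tk <- taskDataset("pure", paste0("c", 1:20), Xs, rep(c(0L, 1L), each = 10),
                    split = rep(rep(c("train", "test"), c(8, 2)), 2))
  lp <- trainLayer(list(tk), NULL, forestParams(nTrees = 1L))
  expect_true(all(scoreAll(lp, Xs) %in% c(0, 1)))
})

test_that("a one-layer model equals independently trained single-task forests", {
  b <- makeTinyBenchmark(nTasks = 3L, n = 80L, m = 64L)
  model <- mtForestNet(b$tasks, params = smallParams, maxLayers = 1L)
  expect_equal(bestLayer(model), 1L)
  for (tk in b$tasks) {
    tr <- splitTags(tk) == "train"
    single <- ranger::ranger(
      x = features(tk)[tr, ], y = factor(taskLabels(tk)[tr], levels = 0:1),
      num.trees = 50L, mtry = floor(log2(64)), probability = TRUE,
      seed = 8L, num.threads = 1L)
    ref <- stats::predict(single, features(tk), num.threads = 1L)$predictions[, "1"]
    got <- scores(predict(model, features(tk),
                          layer = 1L))[, paste0("S_", taskName(tk))]
    expect_identical(unname(got), unname(ref))
  }
})

test_that("fitting is deterministic and layer selection never loses to layer 1", {
  b <- makeTinyBenchmark()
  m1 <- mtForestNet(b$tasks, params = smallParams, maxLayers = 3L)
  m2 <- mtForestNet(b$tasks, params = smallParams, maxLayers = 3L)
  expect_identical(m1@perLayerValidationAUC, m2@perLayerValidationAUC)
  expect_identical(m1@meanValidationAUC, m2@meanValidationAUC)
  expect_gte(m1@meanValidationAUC[bestLayer(m1)], m1@meanValidationAUC[1])
  expect_equal(bestLayer(m1), which.max(m1@meanValidationAUC))
})

test_that("prediction propagates through layers and matches the fit-time cache", {
  b <- makeTinyBenchmark()
  model <- mtForestNet(b$tasks, params = smallParams, maxLayers = 3L)
  for (t in seq_along(b$tasks)) {
    X <- features(b$tasks[[t]])
    got <- scores(predict(model, X))
    expect_equal(unname(got),
                 unname(model@scoreCache[[bestLayer(model)]][[t]]),
                 tolerance = 1e-12)
  }
  # row count conserved, entries bounded
  sm <- predict(model, features(b$tasks[[1]]))
  expect_equal(nrow(scores(sm)), nrow(features(b$tasks[[1]])))
  expect_true(all(scores(sm) >= 0 & scores(sm) <= 1))
  # empty input
  empty <- predict(model, features(b$tasks[[1]])[0, , drop = FALSE])
  expect_equal(nrow(scores(empty)), 0L)
  expect_equal(ncol(scores(empty)), length(taskOrder(model)))
  expect_error(predict(model, features(b$tasks[[1]])[, 1:10]), "width")
})

test_that("evaluation reproduces stored validation AUCs and averages defined tasks", {
  b <- makeTinyBenchmark()
  model <- mtForestNet(b$tasks, params = smallParams, maxLayers = 3L)
  ev <- evaluateModel(model, b$tasks, "validation")
  expect_equal(ev$perTaskAUC,
               model@perLayerValidationAUC[[bestLayer(model)]])
  expect_equal(ev$meanAUC, mean(ev$perTaskAUC, na.rm = TRUE))
  evT <- evaluateModel(model, b$tasks, "test")
  expect_true(all(evT$perTaskAUC >= 0 & evT$perTaskAUC <= 1, na.rm = TRUE))
})

test_that("excluding a dataset group removes its tasks; an empty group is a no-op", {
  b <- makeTinyBenchmark(nTasks = 4L, n = 100L, m = 64L)
  ga <- vapply(b$tasks, function(t) t@group, character(1))
  names(ga) <- vapply(b$tasks, taskName, character(1))
  full <- mtForestNet(b$tasks, params = smallParams, maxLayers = 2L)
  evFull <- evaluateModel(full, b$tasks, "test")
  ab <- ablateDataset(b$tasks, ga, "pool2", params = smallParams,
                      maxLayers = 2L)
  expect_setequal(ab$excludedTasks, names(ga)[ga == "pool2"])
  expect_equal(length(taskOrder(ab$model)), 4L - length(ab$excludedTasks))
  expect_equal(ncol(ab$model@scoreCache[[1]][[1]]),
               length(taskOrder(ab$model)))
  # a declared-but-empty group reproduces the full model
  noop <- ablateDataset(b$tasks, ga, "poolEmpty", params = smallParams,
                        maxLayers = 2L,
                        knownGroups = c(unique(ga), "poolEmpty"))
  expect_equal(noop$evaluation$perTaskAUC, evFull$perTaskAUC)
  expect_error(ablateDataset(b$tasks, ga, "nope", params = smallParams),
               "unknown group")
})

test_that("excluding a task's only correlated partner hurts that task", {
  # two tasks share a pool and a labeling rule; two unrelated tasks apart
  cfg <- generatorConfig(nTasks = 4L, chemicalsPerTask = 150L,
                         featureLength = 128L, poolStructure = "disjoint",
                         nPools = 2L, latentDim = 8L, rho = 0.95,
                         labelNoise = 0.1, seed = 21L)
  tasks <- splitAllTasks(generateTasks(cfg)$tasks, seed = 31L)
  # pools are assigned round-robin: task1/task3 share pool1, task2/task4 pool2
  ga <- c(task1 = "keep", task3 = "partner", task2 = "other", task4 = "other")
  p <- forestParams(nTrees = 150L)
  full <- mtForestNet(tasks, params = p, maxLayers = 3L)
  aucFull <- evaluateModel(full, tasks, "test")$perTaskAUC["task1"]
  ab <- ablateDataset(tasks, ga, "partner", params = p, maxLayers = 3L)
  aucAblated <- ab$evaluation$perTaskAUC["task1"]
  expect_lt(aucAblated, aucFull)
})
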