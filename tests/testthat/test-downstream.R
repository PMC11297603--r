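# A labeled dataset whose signal lives in a few predicted-call (ZF)
# columns while the base fingerprint is pure noise.
makeZFSignalData <- function(n = 200L, m = 64L, nZF = 8L, nInformative = 3L,
                             flip = 0.1, seed = 19L) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1L, 0.5)
    xBase <- matrix(rbinom(n * m, 1L, 0.2), n, m,
                    dimnames = list(NULL, paste0("F", seq_len(m))))
    xZF <- matrix(rbinom(n * nZF, 1L, 0.5), n, nZF,
                  dimnames = list(NULL, paste0("ZF_t", seq_len(nZF))))
    for (j in seq_len(nInformative)) {
      fl <- rbinom(n, 1L, flip)
      xZF[, j] <- ifelse(fl == 1L, 1L - y, y)
    }
    augmentedDataset(paste0("c", seq_len(n)), xBase, xZF, y)
  })
}

test_that("augmentation appends one thresholded call column per task", {
  b <- makeTinyBenchmark(nTasks = 3L, n = 80L, m = 64L)
  model <- mtForestNet(b$tasks, params = smallParams, maxLayers = 2L)
  X <- features(b$tasks[[1]])
  aug <- augmentZF(model, X, y = taskLabels(b$tasks[[1]]))
  expect_equal(ncol(aug@xBase) + ncol(aug@xZF), 64L + 3L)
  expect_true(all(aug@xZF %in% c(0L, 1L)))
  expect_equal(colnames(aug@xZF), paste0("ZF_", taskOrder(model)))
  # calls follow the probability threshold
  sm <- scores(predict(model, X))
  expect_identical(unname(aug@xZF), unname((sm >= 0.5) + 0L))
  aug0 <- augmentZF(model, X, callThreshold = 0)
  expect_true(all(aug0@xZF == 1L))
  expect_error(augmentZF(model, X[, 1:10]), "width")
})

test_that("floating backward selection recovers a planted predictive column", {
  withr::with_seed(55, {
    n <- 120L
    y <- rbinom(n, 1L, 0.5)
    X <- matrix(rbinom(n * 5L, 1L, 0.5), n, 5L,
                dimnames = list(NULL, paste0("C", 1:5)))
    X[, 3] <- y  # perfectly predictive candidate
  })
  sel <- sbfsConditional(X, y, candidateColumns = colnames(X),
                         kFolds = 5L, seed = 2L,
                         params = forestParams(nTrees = 50L))
  expect_true("C3" %in% sel$selected)
  expect_gte(sel$cvAUC, sel$fullSetCvAUC)
  expect_gte(sel$cvAUC, 0.95)
})

test_that("selection returns the full set when every removal hurts", {
  # y needs both columns: an AND of two balanced bits
  withr::with_seed(7, {
    n <- 160L
    a <- rbinom(n, 1L, 0.5); b <- rbinom(n, 1L, 0.5)
    y <- as.integer(a & b)
    if (length(unique(y)) < 2L) y[1] <- 1L - y[1]
    X <- cbind(A = a, B = b)
  })
  sel <- sbfsConditional(X, y, candidateColumns = c("A", "B"),
                         kFolds = 4L, seed = 3L,
                         params = forestParams(nTrees = 50L))
  expect_setequal(sel$selected, c("A", "B"))
  expect_error(sbfsConditional(X, y, candidateColumns = character(0)),
               "non-empty")
})

test_that("degenerate folds raise a stratified-folding error", {
  X <- matrix(rbinom(40, 1, 0.5), 20, 2, dimnames = list(NULL, c("A", "B")))
  y <- c(1L, rep(0L, 19L))   # one positive cannot stratify into 5 folds
  expect_error(sbfsConditional(X, y, candidateColumns = c("A", "B"),
                               kFolds = 5L), "degenerate fold")
})

test_that("repeated evaluation is reproducible and counts selections sanely", {
  d <- makeZFSignalData(n = 120L, m = 32L, nZF = 4L, nInformative = 2L)
  r1 <- repeatedEvaluation(d, runs = 3L, useZF = TRUE, useSelection = TRUE,
                           seed = 5L, params = forestParams(nTrees = 30L),
                           kFolds = 4L)
  r2 <- repeatedEvaluation(d, runs = 3L, useZF = TRUE, useSelection = TRUE,
                           seed = 5L, params = forestParams(nTrees = 30L),
                           kFolds = 4L)
  expect_identical(r1$perRunAUC, r2$perRunAUC)
  expect_identical(r1$selectionFrequency, r2$selectionFrequency)
  expect_true(all(r1$selectionFrequency >= 0 & r1$selectionFrequency <= 1))
  expect_equal(r1$meanAUC, mean(r1$perRunAUC))
  expect_equal(r1$varAUC, stats::var(r1$perRunAUC))
  # no selection frequencies unless selection ran
  r3 <- repeatedEvaluation(d, runs = 2L, useZF = TRUE, useSelection = FALSE,
                           seed = 5L, params = forestParams(nTrees = 30L))
  expect_null(r3$selectionFrequency)
})

test_that("ZF-borne signal lifts AUC only when ZF columns are used", {
  d <- makeZFSignalData(n = 160L, m = 48L, nZF = 6L, nInformative = 2L)
  p <- forestParams(nTrees = 60L)
  with_ <- repeatedEvaluation(d, runs = 5L, useZF = TRUE, seed = 9L,
                              params = p)
  without <- repeatedEvaluation(d, runs = 5L, useZF = FALSE, seed = 9L,
                                params = p)
  expect_gt(with_$meanAUC, without$meanAUC)
})
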