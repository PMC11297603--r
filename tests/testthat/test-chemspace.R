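groupFromIds <- function(name, idSets, fpList = NULL) {
  subsets <- lapply(seq_along(idSets), function(i) {
    s <- list(ids = idSets[[i]])
    if (!is.null(fpList)) s$fingerprints <- fpList[[i]]
    s
  })
  datasetGroup(name, subsets)
}

test_that("tanimoto matches hand-enumerated set arithmetic", {
  a <- c(0, 1, 1, 1, 0); b <- c(0, 0, 1, 1, 1)
  expect_equal(tanimoto(a, b), 0.5)            # |{2,3}| / |{1,2,3,4}|
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)  # all-zero convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("common-chemical percentage takes the max over subset pairs", {
  A <- groupFromIds("A", list(c("c1", "c2")))
  B <- groupFromIds("B", list(c("c2", "c3", "c4")))
  expect_equal(commonChemicalPercentage(A, B), 25)   # 1 shared / 4 unique
  expect_equal(commonChemicalPercentage(A, A), 100)
  D <- groupFromIds("D", list(c("x1"), c("x2", "x3")))
  expect_equal(commonChemicalPercentage(A, D), 0)
  # max over pairs: add a second identical subset
  A2 <- groupFromIds("A2", list(c("c9"), c("c2", "c3", "c4")))
  expect_equal(commonChemicalPercentage(A2, B), 100)
})

test_that("average similarity equals the hand-computed cross-pair mean", {
  fpA <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0))
  fpB <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  A <- groupFromIds("A", list(c("a1", "a2")), list(fpA))
  B <- groupFromIds("B", list(c("b1", "b2")), list(fpB))
  hand <- mean(c(bruteForceTanimoto(fpA[1, ], fpB[1, ]),
                 bruteForceTanimoto(fpA[1, ], fpB[2, ]),
                 bruteForceTanimoto(fpA[2, ], fpB[1, ]),
                 bruteForceTanimoto(fpA[2, ], fpB[2, ])))
  expect_equal(averageSimilarity(A, B), 100 * hand)
  # one identical single-chemical subset on both sides
  S <- groupFromIds("S", list("s1"), list(matrix(c(1, 0, 1, 0), 1)))
  expect_equal(averageSimilarity(S, S), 100)
  # disjoint bit sets
  Z1 <- groupFromIds("Z1", list("z1"), list(matrix(c(1, 1, 0, 0), 1)))
  Z2 <- groupFromIds("Z2", list("z2"), list(matrix(c(0, 0, 1, 1), 1)))
  expect_equal(averageSimilarity(Z1, Z2), 0)
})

test_that("group metrics are symmetric and ordering-invariant", {
  set.seed(9)
  for (i in 1:20) {
    nA <- sample(1:3, 1); nB <- sample(1:3, 1)
    mkGroup <- function(nm, k) {
      idSets <- lapply(seq_len(k), function(j)
        paste0("c", sample(30, sample(2:8, 1))))
      fps <- lapply(idSets, function(ids)
        randomBits(length(ids), 32, seed = sample(1e6, 1)))
      groupFromIds(nm, idSets, fps)
    }
    A <- mkGroup("A", nA); B <- mkGroup("B", nB)
    expect_equal(commonChemicalPercentage(A, B),
                 commonChemicalPercentage(B, A))
    expect_equal(averageSimilarity(A, B), averageSimilarity(B, A))
    expect_equal(commonChemicalPercentage(A, A), 100)
    # subset order and chemical order within subsets do not matter
    Arev <- datasetGroup("A", rev(lapply(A@subsets, function(s) {
      o <- rev(seq_along(s$ids))
      list(ids = s$ids[o], fingerprints = s$fingerprints[o, , drop = FALSE])
    })))
    expect_equal(averageSimilarity(Arev, B), averageSimilarity(A, B))
  }
})

test_that("task label correlations are binned as printed", {
  ids <- paste0("c", 1:5)
  lab <- function(v) stats::setNames(v, ids)
  # identical labels on >= 3 shared chemicals: |r| = 1, very high
  s <- taskCorrelationSummary(list(t1 = lab(c(1, 0, 1, 0, 1)),
                                   t2 = lab(c(1, 0, 1, 0, 1))))
  expect_equal(unname(s$counts["very_high"]), 1L)
  # no shared chemicals: uncategorized
  s2 <- taskCorrelationSummary(list(
    t1 = stats::setNames(c(1, 0, 1), paste0("a", 1:3)),
    t2 = stats::setNames(c(1, 0, 1), paste0("b", 1:3))))
  expect_equal(s2$uncategorized, 1L)
  expect_equal(sum(s2$counts), 0L)
  # hand-computed Pearson on 5 shared chemicals
  x <- c(1, 1, 0, 0, 1); y <- c(1, 0, 0, 1, 1)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  s3 <- taskCorrelationSummary(list(t1 = lab(x), t2 = lab(y)))
  expect_equal(s3$pairs$r, rHand)
  bin <- if (abs(rHand) < 0.3) "low" else if (abs(rHand) < 0.5) "medium" else
    if (abs(rHand) < 0.7) "high" else "very_high"
  expect_equal(unname(s3$counts[bin]), 1L)
  # zero variance in one task: uncategorized
  s4 <- taskCorrelationSummary(list(t1 = lab(c(1, 1, 1, 1, 1)),
                                    t2 = lab(y)))
  expect_equal(s4$uncategorized, 1L)
  expect_error(taskCorrelationSummary(list(a = lab(x), b = lab(y)),
                                      minShared = 2), "minShared")
})

test_that("categorized and uncategorized pairs partition all task pairs", {
  set.seed(4)
  nTasks <- 7
  labs <- lapply(seq_len(nTasks), function(t) {
    ids <- paste0("c", sample(40, sample(3:20, 1)))
    stats::setNames(rbinom(length(ids), 1, 0.5), ids)
  })
  names(labs) <- paste0("t", seq_len(nTasks))
  s <- taskCorrelationSummary(labs)
  expect_equal(sum(s$counts) + s$uncategorized, choose(nTasks, 2))
  expect_equal(nrow(s$pairs), choose(nTasks, 2))
})

test_that("fingerprint PCA reproduces a dense eigendecomposition", {
  # rank-1 data: first component carries all variance
  line <- outer(0:5, c(1, 1, 0, 1))
  p <- pcaProjection(line, 1)
  expect_equal(p$explainedVariance[1], 1)
  expect_equal(sum(p$allExplainedVariance), 1)

  X <- randomBits(10, 16, seed = 77)
  p2 <- pcaProjection(X, 3)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  expect_equal(sum(p2$allExplainedVariance), 1)
  # coordinates reproduce the eigenbasis projection up to sign
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ref <- Xc %*% e$vectors[, 1:3]
  for (j in 1:3)
    expect_lt(min(max(abs(p2$coordinates[, j] - ref[, j])),
                  max(abs(p2$coordinates[, j] + ref[, j]))), 1e-8)
  expect_error(pcaProjection(X[1:2, ], 2), "at least")
})
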