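# Feature clustering and the iterative dendrogram-cut selection engine.

toyMatrix <- function() {
  set.seed(9)
  base <- stats::rnorm(30)
  vals <- cbind(
    f1 = base,
    f2 = base + stats::rnorm(30, sd = 0.01), # near-duplicate of f1
    f3 = stats::rnorm(30),
    f4 = stats::rnorm(30)
  )
  standardizeFeatures(featureMatrix(vals))
}

test_that("feature clustering follows the agglomerative contract", {
  m <- toyMatrix()
  d <- clusterFeatures(m)
  expect_s4_class(d, "FeatureDendrogram")
  expect_equal(nrow(dendrogramMerges(d)), 3) # n - 1 merges
  expect_true(all(diff(d@height) >= -1e-12)) # nondecreasing under average linkage

  # identical columns merge at distance 0
  vals <- featureValues(m)
  dup <- featureMatrix(cbind(vals, f1copy = vals[, "f1"]))
  dup@center <- c(m@center, f1copy = m@center[["f1"]])
  dup@scale <- c(m@scale, f1copy = m@scale[["f1"]])
  dup@standardized <- TRUE
  d2 <- clusterFeatures(dup)
  expect_equal(min(d2@height), 0, tolerance = 1e-12)

  expect_error(clusterFeatures(featureMatrix(vals)), "standardized")
})

test_that("toy merge order equals brute-force agglomeration", {
  m <- toyMatrix()
  d <- clusterFeatures(m, linkage = "average")
  # brute-force average-linkage agglomeration over the 4 columns
  X <- featureValues(m)
  clusters <- as.list(colnames(X))
  dmat <- as.matrix(stats::dist(t(X)))
  mergedPairs <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestD <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (dd < bestD) {
          bestD <- dd
          best <- c(j, i)
        }
      }
    }
    mergedPairs[[length(mergedPairs) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])), h = bestD
    )
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  # compare each hclust merge's member set and height with the oracle
  hc <- d@tree
  leaves <- d@labels
  memberSets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(idx) if (idx < 0) leaves[-idx] else memberSets[[idx]]
    memberSets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    expect_identical(memberSets[[k]], mergedPairs[[k]]$members)
    expect_equal(hc$height[k], mergedPairs[[k]]$h, tolerance = 1e-12)
  }
})

test_that("dendrogram cuts partition leaves by threshold", {
  m <- toyMatrix()
  d <- clusterFeatures(m)
  expect_length(cutDendrogram(d, 0), 4) # all singletons
  expect_length(cutDendrogram(d, max(d@height) + 1), 1)
  mid <- mean(d@height[1:2])
  cl <- cutDendrogram(d, mid)
  # manual trace: merges below `mid` joined, others separate
  expect_true(any(vapply(cl, function(g) setequal(g, c("f1", "f2")), logical(1))))
  expect_length(cl, 3)
  expect_error(cutDendrogram(d, -1), ">= 0")
})

test_that("iterative selection keeps informative features and drops duplicates", {
  set.seed(21)
  n <- 80
  x1 <- stats::rnorm(n)
  x3 <- stats::rnorm(n)
  labels <- ifelse(x1 + x3 > 0, "a", "b")
  vals <- cbind(
    f1 = x1, f2 = x1 + stats::rnorm(n, sd = 1e-3),
    f3 = x3, f4 = stats::rnorm(n), f5 = stats::rnorm(n)
  )
  m <- standardizeFeatures(featureMatrix(vals))
  # deterministic evaluator: leave-one-out nearest-centroid accuracy with a
  # small parsimony penalty, so redundant duplicates are strictly droppable
  evalr <- function(featNames) {
    X <- featureValues(m)[, featNames, drop = FALSE]
    correct <- 0
    for (i in seq_len(n)) {
      ca <- colMeans(X[labels == "a" & seq_len(n) != i, , drop = FALSE])
      cb <- colMeans(X[labels == "b" & seq_len(n) != i, , drop = FALSE])
      pred <- if (sum((X[i, ] - ca)^2) < sum((X[i, ] - cb)^2)) "a" else "b"
      correct <- correct + (pred == labels[i])
    }
    correct / n - 0.001 * length(featNames)
  }
  res <- iterativeSelect(m, labels, evalr)
  expect_true(all(c("f1", "f3") %in% res$selected) ||
    all(c("f2", "f3") %in% res$selected)) # duplicate may stand in for f1
  expect_false(all(c("f1", "f2") %in% res$selected)) # duplicates collapsed
  expect_gte(res$score, res$fullScore - 1e-6) # selection never hurts
  expect_true(all(c("threshold", "candidate", "score", "accepted") %in% names(res$trace)))

  # constant evaluator: nothing improves, full set returned
  resConst <- iterativeSelect(m, labels, function(f) 0.5)
  expect_identical(resConst$selected, colnames(vals))

  # reproducibility: same inputs, same outcome
  res2 <- iterativeSelect(m, labels, evalr)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$trace, res2$trace)

  # empty thresholds: all features unchanged
  res3 <- iterativeSelect(m, labels, evalr, thresholds = numeric(0))
  expect_identical(res3$selected, colnames(vals))
})
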