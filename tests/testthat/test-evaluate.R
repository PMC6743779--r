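# brute-force oracle: per-point enumeration of neighbors with the same
# deterministic tie rules (distance ties by row index, vote ties by smallest
# sorted class)
knnOracle <- function(m, labels, k) {
  n <- nrow(m)
  classes <- sort(unique(labels))
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(min(k, n - 1))]
    counts <- vapply(classes, function(cl) sum(labels[nb] == cl), 0L)
    pred[i] <- classes[which.max(counts)]
  }
  pred
}

test_that("kNN predictions equal brute-force enumeration on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(8:50, 1)
    p <- sample(2:5, 1)
    k <- sample(c(1, 3, 5, 11), 1)
    # lattice coordinates provoke exact distance ties
    m <- matrix(sample(0:3, n * p, replace = TRUE), n, p)
    labels <- sample(letters[1:3], n, replace = TRUE)
    while (length(unique(labels)) < 2)
      labels <- sample(letters[1:3], n, replace = TRUE)
    got <- suppressWarnings(knnLooBalancedAccuracy(m, labels, k = k))
    expect_identical(got$predictions, knnOracle(m, labels, k))
  }
})

test_that("balanced accuracy is the unweighted mean of per-class recalls", {
  # two separable clouds: perfect accuracy at k = 1
  m <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10))
  labels <- rep(c("a", "b"), each = 10)
  r <- suppressWarnings(knnLooBalancedAccuracy(m, labels, k = 1))
  expect_identical(r$balancedAccuracy, 1)
  # chance level for shuffled balanced labels
  set.seed(42)
  accs <- replicate(8, {
    mm <- matrix(rnorm(120 * 3), 120, 3)
    suppressWarnings(knnLooBalancedAccuracy(
      mm, sample(rep(c("a", "b"), 60)), k = 11))$balancedAccuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  expect_error(knnLooBalancedAccuracy(m, labels[-1], k = 1), "labels")
})

test_that("image pair distance is the mean over the full cross product", {
  expect_identical(imagePairDistance(matrix(c(0, 0), 1),
                                     matrix(c(3, 4), 1)), 5)
  a <- matrix(rnorm(10), 5, 2)
  expect_equal(imagePairDistance(a, a[1, , drop = FALSE]),
               imagePairDistance(a[1, , drop = FALSE], a))
  expect_identical(imagePairDistance(matrix(1, 1, 2), matrix(1, 1, 2)), 0)
  expect_error(imagePairDistance(a[0, , drop = FALSE], a), "empty")
  # hand-computed 2x2 cross product
  b <- matrix(c(0, 0, 0, 1), 2, 2, byrow = TRUE)
  cc <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(imagePairDistance(b, cc),
               mean(c(1, sqrt(2), sqrt(2), 1)))
})

test_that("same-term distance score has its fixed points and null behavior", {
  set.seed(7)
  # three images per term, two terms, cells drawn from term-specific centers
  nI <- 8
  feats <- NULL
  ids <- NULL
  terms <- character(0)
  for (i in seq_len(nI)) {
    t <- if (i <= nI / 2) "alpha" else "beta"
    mu <- if (t == "alpha") 0 else 3
    feats <- rbind(feats, matrix(rnorm(10 * 2, mu), 10, 2))
    ids <- c(ids, rep(sprintf("img%d", i), 10))
    terms[sprintf("img%d", i)] <- t
  }
  cfg <- pairDistanceConfig(nSamePairs = 300, nDiffPairsPerTerm = 300,
                            seed = 5)
  r <- normalizedSameTermDistance(standardizeFeatures(feats), ids, terms,
                                  config = cfg)
  expect_true(all(r$perTerm$score < 0))   # same-term images are closer
  expect_equal(r$overall, mean(r$perTerm$score))
  # shuffled terms: score near zero
  set.seed(11)
  shuf <- stats::setNames(sample(terms), names(terms))
  r0 <- normalizedSameTermDistance(standardizeFeatures(feats), ids, shuf,
                                   config = cfg)
  expect_lt(abs(r0$overall), 0.15)
  # a term with one image is skipped with a warning
  t2 <- terms
  t2["img1"] <- "gamma"
  expect_warning(normalizedSameTermDistance(standardizeFeatures(feats), ids,
                                            t2, config = cfg), "single image")
})

test_that("the distance score is invariant to uniform affine feature rescaling", {
  set.seed(3)
  feats <- matrix(rnorm(200), 50, 4)
  ids <- rep(sprintf("i%d", 1:10), each = 5)
  terms <- stats::setNames(rep(c("a", "b"), 5), sprintf("i%d", 1:10))
  cfg <- pairDistanceConfig(nSamePairs = 100, nDiffPairsPerTerm = 100,
                            seed = 2)
  r1 <- normalizedSameTermDistance(feats, ids, terms, config = cfg)
  r2 <- normalizedSameTermDistance(feats * 7 , ids, terms, config = cfg)
  expect_equal(r1$overall, r2$overall, tolerance = 1e-12)
})

test_that("multiloc scores are signed log ratios with exact antisymmetry", {
  A <- matrix(c(0, 0), 1)
  B <- matrix(c(2, 0), 1)
  # equidistant cell scores zero
  expect_equal(multilocScore(c(1, 5), A, B), 0)
  # closer to B means positive (sign convention)
  expect_gt(multilocScore(c(1.9, 0), A, B), 0)
  expect_lt(multilocScore(c(0.1, 0), A, B), 0)
  cells <- matrix(rnorm(20), 10, 2)
  expect_equal(multilocScore(cells, A, B), -multilocScore(cells, B, A))
  expect_warning(s <- multilocScore(c(0, 0), A, B), "centroid")
  expect_identical(s, -Inf)
})

test_that("variability statistic ranks images by population sd", {
  scores <- c(-1, 1, 0, 0, 0.5, 0.5, 2)
  ids <- c("hi", "hi", "lo", "lo", "mid", "mid", "solo")
  expect_warning(v <- variabilityStatistic(scores, ids), "excluded")
  expect_identical(v$image_id, c("hi", "lo", "mid"))
  expect_equal(v$sd, c(1, 0, 0))
  expect_equal(v$mean[1], 0)
})

test_that("hierarchical clustering is deterministic with a Newick export", {
  m <- rbind(c(0, 0), c(0, 0), c(5, 5))
  rownames(m) <- c("x1", "x2", "far")
  r <- hierarchicalCluster(m, k = 2)
  # coincident pair merges first
  expect_identical(sort(r$hclust$merge[1, ]), c(-2L, -1L))
  expect_identical(unname(r$clusters["x1"]), unname(r$clusters["x2"]))
  expect_false(r$clusters["x1"] == r$clusters["far"])
  expect_match(r$newick, "^\\(")
  expect_true(grepl("far", r$newick))
  # two rows merge at their Euclidean distance (single merge)
  r2 <- hierarchicalCluster(rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(r2$hclust$height, 5)
  expect_error(hierarchicalCluster(m[1, , drop = FALSE]), ">= 2 rows")
  expect_error(hierarchicalCluster(rbind(c(1, Inf), c(0, 0))), "non-finite")
})

test_that("clustering recovers planted groups and matches an independent ARI", {
  skip_if_not_installed("mclust")
  set.seed(21)
  m <- rbind(matrix(rnorm(40, 0, 0.3), 20),
             matrix(rnorm(40, 4, 0.3), 20),
             matrix(rnorm(40, 8, 0.3), 20))
  truth <- rep(1:3, each = 20)
  r <- hierarchicalCluster(m, k = 3)
  ari <- mclust::adjustedRandIndex(r$clusters, truth)
  expect_gte(ari, 0.99)
})
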