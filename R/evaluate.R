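#' @include features.R
NULL

.asFeatureMatrix <- function(x) {
  if (is(x, "FeatureTable")) featureMatrix(x) else as.matrix(x)
}

#' Leave-one-out kNN balanced accuracy
#'
#' Predicts each cell's label by majority vote of its k nearest Euclidean
#' neighbors (excluding itself) and reports the balanced accuracy — the
#' unweighted mean of per-class recalls. Vote ties break deterministically to
#' the smallest class after sorting class names; distance ties at the
#' neighborhood boundary break by smaller row index.
#'
#' @param features a \linkS4class{FeatureTable} or matrix (standardize
#'   first; see \code{\link{standardizeFeatures}}).
#' @param labels character vector, one label per row.
#' @param k neighborhood size (default 11, the protocol's best setting).
#' @return A list: \code{balancedAccuracy}, \code{perClass} recalls,
#'   \code{confusion} table, and per-cell \code{predictions}.
#' @export
knnLooBalancedAccuracy <- function(features, labels, k = 11) {
  m <- .asFeatureMatrix(features)
  n <- nrow(m)
  if (length(labels) != n || anyNA(labels))
    stop("contract error: labels must be complete and aligned with rows")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  small <- names(which(table(labels) < k + 1))
  if (length(small))
    warning("class(es) with fewer than k+1 members: ",
            paste(small, collapse = ", "))
  D <- as.matrix(stats::dist(m))
  diag(D) <- Inf
  pred <- character(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ], seq_len(n))[seq_len(min(k, n - 1L))]
    votes <- table(factor(labels[nb], levels = classes))
    pred[i] <- classes[which.max(votes)]   # first max = smallest sorted class
  }
  conf <- table(truth = factor(labels, classes), pred = factor(pred, classes))
  recalls <- diag(conf) / rowSums(conf)
  list(balancedAccuracy = mean(recalls), perClass = recalls,
       confusion = conf, predictions = pred)
}

#' Per-layer kNN accuracy sweep
#'
#' Extracts features from each named layer, standardizes them freshly, and
#' runs the leave-one-out kNN classifier, yielding a layer-by-accuracy
#' report.
#'
#' @param model an \linkS4class{InpaintingModel}.
#' @param crops a \linkS4class{CellCropSet}.
#' @param labels per-cell labels, or a character vector named by image_id.
#' @param layers layer names to sweep.
#' @param k kNN neighborhood size.
#' @return data.frame(layer, balancedAccuracy).
#' @export
layerSweep <- function(model, crops, labels, layers = paste0("Conv", 1:5),
                       k = 11) {
  cd <- cropData(crops)
  if (!is.null(names(labels)))
    labels <- unname(labels[as.character(cd$image_id)])
  if (anyNA(labels) || length(labels) != nrow(cd))
    stop("contract error: labels missing for some cells")
  acc <- vapply(layers, function(ly) {
    ft <- standardizeFeatures(extractFeatures(model, crops, layer = ly))
    knnLooBalancedAccuracy(ft, labels, k = k)$balancedAccuracy
  }, numeric(1))
  data.frame(layer = layers, balancedAccuracy = unname(acc))
}

#' Mean cross-image pairwise cell distance
#'
#' The average Euclidean distance over the full cross-product of cells of
#' the first image with cells of the second.
#'
#' @param cellsA,cellsB feature matrices (cells x features), standardized.
#' @return A non-negative scalar; symmetric in its arguments.
#' @export
imagePairDistance <- function(cellsA, cellsB) {
  a <- .asFeatureMatrix(cellsA)
  b <- .asFeatureMatrix(cellsB)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("contract error: empty cell set")
  cross <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  mean(sqrt(pmax(cross, 0)))
}

#' Pair-distance sampling configuration
#'
#' @param nSamePairs same-term image pairs sampled per term (default 1000).
#' @param nDiffPairsPerTerm pairs sampled against each other term.
#' @param seed dedicated sampling seed (reported with the scores).
#' @export
pairDistanceConfig <- function(nSamePairs = 1000, nDiffPairsPerTerm = 1000,
                               seed = 1) {
  stopifnot(nSamePairs >= 1, nDiffPairsPerTerm >= 1)
  list(nSamePairs = as.integer(nSamePairs),
       nDiffPairsPerTerm = as.integer(nDiffPairsPerTerm),
       seed = as.integer(seed))
}

# all-pairs image distance matrix from a standardized cell feature table
.imageDistanceMatrix <- function(features, imageIds) {
  m <- .asFeatureMatrix(features)
  ids <- unique(imageIds)
  groups <- lapply(ids, function(i) m[imageIds == i, , drop = FALSE])
  names(groups) <- ids
  k <- length(ids)
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- imagePairDistance(groups[[i]], groups[[j]])
    }
  }
  D
}

#' Normalized same-term pairwise distance score
#'
#' For each localization term, samples image pairs sharing the term and
#' pairs across terms, and normalizes the same-term mean distance against
#' the different-term expectation: \code{(meanSame - meanDiff) / meanDiff}.
#' A negative score means cells of same-term images are closer in the
#' feature space than expected. The \code{"balanced"} variant samples
#' \code{nDiffPairsPerTerm} pairs against each other term (controlling class
#' imbalance); the \code{"pooled"} variant draws all different-term pairs
#' from the pooled set of other terms, optionally constrained to same or
#' different cell lines, and reports a single overall score.
#'
#' @param features standardized per-cell features
#'   (\linkS4class{FeatureTable} or matrix).
#' @param imageIds per-cell image ids (taken from a FeatureTable's keys when
#'   omitted).
#' @param terms character vector of localization terms named by image_id.
#' @param config from \code{\link{pairDistanceConfig}}.
#' @param variant \code{"balanced"} or \code{"pooled"}.
#' @param normalization \code{"ratio"} (default) or \code{"zscore"}
#'   ((meanSame - meanDiff) / sdDiff).
#' @param cellLines optional cell lines named by image_id (pooled variant).
#' @param cellLineConstraint \code{"none"}, \code{"same"} or
#'   \code{"different"} (pooled variant).
#' @return A list: \code{perTerm} data.frame (term, score, meanSame,
#'   meanDiff, nImages), \code{overall} (mean per-term score, or the single
#'   pooled score), and the sampling \code{seed}.
#' @export
normalizedSameTermDistance <- function(features, imageIds = NULL, terms,
                                       config = pairDistanceConfig(),
                                       variant = c("balanced", "pooled"),
                                       normalization = c("ratio", "zscore"),
                                       cellLines = NULL,
                                       cellLineConstraint = c("none", "same",
                                                              "different")) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  cellLineConstraint <- match.arg(cellLineConstraint)
  if (is.null(imageIds)) {
    stopifnot(is(features, "FeatureTable"))
    imageIds <- cellKeys(features)$image_id
  }
  D <- .imageDistanceMatrix(features, imageIds)
  ids <- rownames(D)
  tm <- terms[ids]
  if (anyNA(tm)) stop("contract error: term missing for some image(s)")
  set.seed(config$seed)
  samplePairs <- function(ia, ib, n) {
    # sample n (a, b) pairs with a != b; ia/ib index D
    a <- ia[sample.int(length(ia), n, replace = TRUE)]
    b <- ib[sample.int(length(ib), n, replace = TRUE)]
    clash <- a == b
    while (any(clash)) {
      b[clash] <- ib[sample.int(length(ib), sum(clash), replace = TRUE)]
      clash <- a == b
    }
    D[cbind(a, b)]
  }
  termLevels <- sort(unique(tm))
  if (variant == "balanced") {
    perTerm <- NULL
    for (t in termLevels) {
      it <- which(tm == t)
      if (length(it) < 2L) {
        warning("term '", t, "' has a single image; skipped")
        next
      }
      same <- samplePairs(it, it, config$nSamePairs)
      diffs <- unlist(lapply(setdiff(termLevels, t), function(o)
        samplePairs(it, which(tm == o), config$nDiffPairsPerTerm)))
      meanSame <- mean(same)
      meanDiff <- mean(diffs)
      score <- if (normalization == "ratio")
        (meanSame - meanDiff) / meanDiff else
          (meanSame - meanDiff) / stats::sd(diffs)
      perTerm <- rbind(perTerm, data.frame(
        term = t, score = score, meanSame = meanSame, meanDiff = meanDiff,
        nImages = length(it)))
    }
    list(perTerm = perTerm, overall = mean(perTerm$score),
         seed = config$seed)
  } else {
    cl <- if (is.null(cellLines)) rep("", length(ids)) else cellLines[ids]
    nPair <- config$nSamePairs
    drawConstrained <- function(sameTerm) {
      out <- numeric(0)
      guard <- 0L
      while (length(out) < nPair) {
        guard <- guard + 1L
        if (guard > 200L) stop("could not satisfy sampling constraints")
        a <- sample.int(length(ids), nPair, replace = TRUE)
        b <- sample.int(length(ids), nPair, replace = TRUE)
        ok <- a != b &
          (if (sameTerm) tm[a] == tm[b] else tm[a] != tm[b])
        if (cellLineConstraint == "same") ok <- ok & cl[a] == cl[b]
        if (cellLineConstraint == "different") ok <- ok & cl[a] != cl[b]
        out <- c(out, D[cbind(a[ok], b[ok])])
      }
      out[seq_len(nPair)]
    }
    same <- drawConstrained(TRUE)
    diffs <- drawConstrained(FALSE)
    meanSame <- mean(same)
    meanDiff <- mean(diffs)
    score <- if (normalization == "ratio")
      (meanSame - meanDiff) / meanDiff else
        (meanSame - meanDiff) / stats::sd(diffs)
    list(perTerm = NULL, overall = score, meanSame = meanSame,
         meanDiff = meanDiff, seed = config$seed)
  }
}

#' Multi-localization log-ratio score
#'
#' For each cell, the log ratio of its feature-space distance to the mean
#' feature vector of compartment A over its distance to the mean of
#' compartment B. Negative scores mean the cell is closer to the first
#' compartment; \code{multilocScore(c, A, B) == -multilocScore(c, B, A)}.
#'
#' @param cells feature matrix (or single vector) of the cells to score.
#' @param compartmentA,compartmentB feature matrices of single cells from
#'   images annotated to each compartment alone.
#' @return A numeric vector of per-cell scores (signed infinity, with a
#'   warning, for a cell exactly at a centroid).
#' @export
multilocScore <- function(cells, compartmentA, compartmentB) {
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  cells <- .asFeatureMatrix(cells)
  a <- colMeans(.asFeatureMatrix(compartmentA))
  b <- colMeans(.asFeatureMatrix(compartmentB))
  dA <- sqrt(rowSums(sweep(cells, 2L, a)^2))
  dB <- sqrt(rowSums(sweep(cells, 2L, b)^2))
  if (any(dA == 0 | dB == 0))
    warning("cell exactly at a compartment centroid: infinite score")
  log(dA / dB)
}

#' Per-image variability of single-cell scores
#'
#' Groups per-cell scores by image and reports each image's mean and
#' population standard deviation, ranked by decreasing standard deviation —
#' the screen used to flag images with single-cell variability.
#'
#' @param scores numeric per-cell scores.
#' @param imageIds per-cell image ids.
#' @return data.frame(image_id, mean, sd, n) sorted by decreasing sd;
#'   single-cell images are excluded with a warning.
#' @export
variabilityStatistic <- function(scores, imageIds) {
  stopifnot(length(scores) == length(imageIds))
  sp <- split(scores, imageIds)
  singles <- names(sp)[lengths(sp) < 2L]
  if (length(singles))
    warning("image(s) with a single cell excluded: ",
            paste(singles, collapse = ", "))
  sp <- sp[lengths(sp) >= 2L]
  out <- data.frame(
    image_id = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) sqrt(mean((v - mean(v))^2)), numeric(1)),
    n = lengths(sp))
  out <- out[order(-out$sd), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agglomerative hierarchical clustering of feature vectors
#'
#' Deterministic agglomerative clustering on Euclidean distances (Ward by
#' default; average and complete linkage available), with a Newick export of
#' the merge tree and optional flat clusters at a count or height cut.
#'
#' @param features feature matrix (rows are cells or proteins; row names
#'   label the tree leaves) or \linkS4class{FeatureTable}.
#' @param linkage \code{"ward"}, \code{"average"} or \code{"complete"}.
#' @param k number of flat clusters to cut, or NULL.
#' @param h cut height, or NULL.
#' @return A list: \code{hclust}, \code{newick} string, \code{clusters}
#'   (named integer vector or NULL), \code{order} (leaf ordering).
#' @export
hierarchicalCluster <- function(features, linkage = c("ward", "average",
                                                      "complete"),
                                k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  m <- .asFeatureMatrix(features)
  if (is(features, "FeatureTable") && is.null(rownames(m)))
    rownames(m) <- cellKeys(features)$cell_id
  if (nrow(m) < 2L) stop("contract error: need >= 2 rows to cluster")
  if (!all(is.finite(m)))
    stop("contract error: non-finite feature values")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  hc <- stats::hclust(stats::dist(m), method = method)
  clusters <- if (!is.null(k) || !is.null(h))
    stats::cutree(hc, k = k, h = h) else NULL
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)),
       clusters = clusters, order = hc$order)
}
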