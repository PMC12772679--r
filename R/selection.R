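#' Agglomerative clustering of standardized features
#'
#' Clusters feature columns with agglomerative hierarchical clustering; the
#' distance between two features is the Euclidean distance between their
#' standardized case-vectors. Default linkage is average (configurable).
#'
#' @param m A standardized [FeatureMatrix-class] with at least 2 features.
#' @param linkage One of `"average"`, `"single"`, `"complete"`, `"ward"`.
#' @return A [FeatureDendrogram-class].
#' @export
clusterFeatures <- function(m, linkage = c("average", "single", "complete", "ward")) {
  stopifnot(is(m, "FeatureMatrix"))
  linkage <- match.arg(linkage)
  if (!isStandardized(m)) {
    stop("clusterFeatures requires a standardized FeatureMatrix (see standardizeFeatures)")
  }
  if (ncol(m@values) < 2) stop("need at least 2 features to cluster")
  d <- stats::dist(t(m@values), method = "euclidean")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  new("FeatureDendrogram",
    merge = hc$merge, height = hc$height,
    labels = hc$labels, linkage = linkage, tree = hc
  )
}

#' Cut a feature dendrogram at a distance threshold
#'
#' Clusters are the connected components of merges strictly below the
#' threshold: threshold 0 yields all singletons, a threshold above the last
#' merge yields one cluster.
#'
#' @param d A [FeatureDendrogram-class].
#' @param threshold Non-negative merge distance.
#' @return Named list of character vectors (feature names per cluster).
#' @export
cutDendrogram <- function(d, threshold) {
  stopifnot(is(d, "FeatureDendrogram"))
  if (threshold < 0) stop("threshold must be >= 0")
  # cutree(h = h) joins merges with height <= h; "strictly below" via nudge
  eps <- 1e-12 * max(1, abs(threshold))
  grp <- stats::cutree(d@tree, h = threshold - eps)
  split(names(grp), grp)
}

#' Iterative dendrogram-cut feature selection
#'
#' Greedy pruning over a descending threshold schedule: at each threshold the
#' features are partitioned by [cutDendrogram()], each cluster collapses to a
#' single representative (the member with the highest single-feature
#' evaluator score; ties broken by canonical name order), and the candidate
#' subset replaces the current one only if the evaluator improves strictly
#' (tolerance 1e-6). The evaluator must be deterministic under a fixed seed.
#'
#' @param m A standardized [FeatureMatrix-class].
#' @param labels Class labels, one per case.
#' @param evaluator `function(featureNames)` returning a scalar score (e.g.
#'   cross-validated accuracy of a classifier restricted to those features).
#' @param thresholds Descending distance schedule; default: the sorted unique
#'   merge heights of the dendrogram, descending.
#' @param linkage Linkage passed to [clusterFeatures()].
#' @return List with `selected` (character vector), `score`, `fullScore`, and
#'   `trace` (data frame of every threshold with candidate subset, score and
#'   accept flag).
#' @export
iterativeSelect <- function(m, labels, evaluator, thresholds = NULL,
                            linkage = "average") {
  stopifnot(is(m, "FeatureMatrix"))
  allFeatures <- colnames(m@values)
  dend <- clusterFeatures(m, linkage = linkage)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(dend@height), decreasing = TRUE)
  }
  current <- allFeatures
  fullScore <- evaluator(allFeatures)
  currentScore <- fullScore
  if (length(thresholds) == 0) {
    return(list(
      selected = current, score = currentScore, fullScore = fullScore,
      trace = data.frame(
        threshold = numeric(0), candidate = character(0),
        score = numeric(0), accepted = logical(0)
      )
    ))
  }
  # single-feature scores fixed once; representative = best-scoring member
  singleScores <- vapply(allFeatures, function(f) evaluator(f), numeric(1))
  trace <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[[i]]
    clusters <- cutDendrogram(dend, th)
    reps <- vapply(clusters, function(members) {
      members <- sort(members) # canonical order breaks ties
      members[which.max(singleScores[members])]
    }, character(1))
    candidate <- intersect(allFeatures, unname(reps)) # registry order
    candScore <- evaluator(candidate)
    accepted <- candScore > currentScore + 1e-6
    if (accepted) {
      current <- candidate
      currentScore <- candScore
    }
    trace[[i]] <- data.frame(
      threshold = th,
      candidate = paste(candidate, collapse = "|"),
      score = candScore, accepted = accepted,
      stringsAsFactors = FALSE
    )
  }
  list(
    selected = current, score = currentScore, fullScore = fullScore,
    trace = do.call(rbind, trace)
  )
}

#' Write a selection trace as CSV
#'
#' @param result Return value of [iterativeSelect()].
#' @param path CSV path.
#' @export
writeSelectionTrace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a dendrogram's merge list
#'
#' @param d A [FeatureDendrogram-class].
#' @return Data frame of (cluster_a, cluster_b, merge_distance) triples in
#'   nondecreasing distance order; negative indices denote leaves as in
#'   [stats::hclust()].
#' @export
dendrogramMerges <- function(d) {
  stopifnot(is(d, "FeatureDendrogram"))
  data.frame(
    cluster_a = d@merge[, 1], cluster_b = d@merge[, 2],
    merge_distance = d@height
  )
}
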