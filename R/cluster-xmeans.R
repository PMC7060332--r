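#' X-means clustering of gene profiles
#'
#' K-means whose cluster number is chosen by BIC-scored splitting: starting
#' from `k_min` centers, each cluster is tentatively split in two
#' (2-means on its members) and the split is kept when the two-cluster
#' model's BIC for that region exceeds the one-cluster model's. Splitting
#' repeats until no split is accepted or `k_max` is reached. The BIC uses
#' a spherical Gaussian likelihood with a common variance per model region
#' and `k * (d + 1)` free parameters for `k` clusters in `d` dimensions.
#'
#' @param em [expr_matrix] or numeric matrix; rows (genes) are the points.
#' @param k_min,k_max Cluster-count bounds; defaults 2 and 20.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Restarts per k-means call; default 10.
#' @return A list of class `xmeans_result`: `k`, `assignment` (named
#'   integer vector gene -> cluster), `centers` (k x samples matrix),
#'   `tot_withinss`.
#' @export
xmeans_cluster <- function(em, k_min = 2, k_max = 20, seed = 1, nstart = 10) {
  vals <- if (inherits(em, "expr_matrix")) em$values else em
  if (k_max < k_min) stop("k_max must be >= k_min")
  n <- nrow(vals)
  if (n < k_min) stop("fewer genes than k_min")
  set.seed(as.integer(seed))
  assignment <- safe_kmeans(vals, k_min, nstart)
  repeat {
    k <- max(assignment)
    accepted <- FALSE
    for (cl in seq_len(k)) {
      if (max(assignment) >= k_max) break
      idx <- which(assignment == cl)
      if (length(idx) < 2L) next
      sub <- vals[idx, , drop = FALSE]
      if (nrow(unique(sub)) < 2L) next
      split2 <- safe_kmeans(sub, 2L, nstart)
      if (region_bic(sub, split2) > region_bic(sub, rep(1L, nrow(sub)))) {
        assignment[idx[split2 == 2L]] <- max(assignment) + 1L
        accepted <- TRUE
      }
    }
    if (!accepted || max(assignment) >= k_max) break
  }
  k <- max(assignment)
  centers <- t(vapply(seq_len(k),
                      function(cl) colMeans(vals[assignment == cl, , drop = FALSE]),
                      numeric(ncol(vals))))
  colnames(centers) <- colnames(vals)
  tot_within <- sum((vals - centers[assignment, , drop = FALSE])^2)
  structure(list(k = k,
                 assignment = stats::setNames(assignment, rownames(vals)),
                 centers = centers,
                 tot_withinss = tot_within),
            class = "xmeans_result")
}

# k-means that tolerates the degenerate inputs stats::kmeans rejects:
# n == k (each point its own cluster) and fewer distinct rows than
# centers (even deterministic partition)
safe_kmeans <- function(x, k, nstart) {
  if (nrow(x) == k) return(seq_len(k))
  if (nrow(unique(x)) < k)
    return(rep_len(seq_len(k), nrow(x)))
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart,
                                       iter.max = 50L))
  km$cluster
}

#' BIC of a spherical-Gaussian k-cluster model of a point region
#'
#' @param x Points (rows) of the region.
#' @param assignment Integer cluster labels (1..k) for the rows of `x`.
#' @return The BIC (larger is better): maximized log-likelihood minus
#'   `p/2 * log(n)` with `p = k * (d + 1)`.
#' @export
region_bic <- function(x, assignment) {
  n <- nrow(x); d <- ncol(x); k <- max(assignment)
  sizes <- tabulate(assignment, nbins = k)
  centers <- t(vapply(seq_len(k),
                      function(cl) colMeans(x[assignment == cl, , drop = FALSE]),
                      numeric(d)))
  rss <- sum((x - centers[assignment, , drop = FALSE])^2)
  sigma2 <- rss / (d * max(n - k, 1L))
  sigma2 <- max(sigma2, 1e-12)
  ll <- sum(sizes * log(sizes / n)) -
    n * d / 2 * log(2 * pi * sigma2) -
    d * (n - k) / 2
  ll - k * (d + 1) / 2 * log(n)
}

#' Per-condition cluster centers
#'
#' Mean z-value of each cluster's member genes within each condition
#' (averaging over the condition's replicate samples).
#'
#' @param xm [xmeans_cluster()] result.
#' @param em The [expr_matrix] that was clustered (provides the design).
#' @return Numeric matrix, clusters x conditions.
#' @export
cluster_condition_centers <- function(xm, em) {
  stopifnot(inherits(em, "expr_matrix"))
  conds <- unique(unname(em$condition))
  out <- vapply(conds, function(cc) {
    cols <- names(em$condition)[em$condition == cc]
    vapply(seq_len(xm$k), function(cl) {
      mean(em$values[names(xm$assignment)[xm$assignment == cl], cols])
    }, numeric(1L))
  }, numeric(xm$k))
  if (xm$k == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, conds))
  rownames(out) <- seq_len(xm$k)
  out
}

#' Label clusters as hyper cluster A, B, or none
#'
#' With center differences `d1 = center(NMDA-saline) - center(non-treat)`,
#' `d2 = center(KUS121) - center(NMDA-saline)`,
#' `d3 = center(KUS187) - center(NMDA-saline)`, a cluster is labelled
#' `A` when `d1 > delta`, `d2 < -delta` and `d3 < -delta` (injury-induced
#' upregulation reversed by both treatments) and `B` when all three
#' differences exceed `delta` (upregulation amplified). All inequalities
#' are strict.
#'
#' @param centers Clusters x conditions matrix from
#'   [cluster_condition_centers()].
#' @param delta Z-value threshold on center differences; default 0.2.
#' @param conditions The four condition names, in design order.
#' @return Character vector of labels (`"A"`, `"B"`, `"none"`), one per
#'   cluster.
#' @export
assign_hyperclusters <- function(centers, delta = 0.2,
                                 conditions = c("non-treat", "NMDA-saline",
                                                "KUS121", "KUS187")) {
  if (!all(conditions %in% colnames(centers)))
    stop("missing condition center: ",
         paste(setdiff(conditions, colnames(centers)), collapse = ", "))
  d1 <- centers[, conditions[2L]] - centers[, conditions[1L]]
  d2 <- centers[, conditions[3L]] - centers[, conditions[2L]]
  d3 <- centers[, conditions[4L]] - centers[, conditions[2L]]
  unname(ifelse(d1 > delta & d2 < -delta & d3 < -delta, "A",
                ifelse(d1 > delta & d2 > delta & d3 > delta, "B", "none")))
}

#' Order genes and samples for heatmap export
#'
#' Rows are ordered by cluster, then by within-cluster Euclidean distance
#' to the cluster center; columns follow the sample dendrogram's leaf
#' order. Values are passed through unchanged.
#'
#' @param em [expr_matrix] of z-scores.
#' @param hc Sample dendrogram from [hcluster_samples()].
#' @param xm [xmeans_cluster()] result on the same genes.
#' @return List with `values` (reordered matrix), `row_order`,
#'   `col_order` (character vectors of ids).
#' @export
export_heatmap_data <- function(em, hc, xm) {
  stopifnot(inherits(em, "expr_matrix"))
  col_order <- hc$labels[hc$order]
  genes <- names(xm$assignment)
  dist_to_center <- vapply(seq_along(genes), function(i) {
    cl <- xm$assignment[i]
    sqrt(sum((em$values[genes[i], ] - xm$centers[cl, ])^2))
  }, numeric(1L))
  row_order <- genes[order(xm$assignment, dist_to_center)]
  list(values = em$values[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order)
}
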