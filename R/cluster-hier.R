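#' Hierarchically cluster samples
#'
#' Agglomerative clustering of the matrix columns (samples) under
#' Euclidean distance between column vectors. The linkage defaults to
#' average, the convention for bootstrapped sample dendrograms.
#'
#' @param em [expr_matrix] or numeric matrix (genes x samples), at least
#'   two columns.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `hclust` over the samples.
#' @export
hcluster_samples <- function(em, linkage = "average") {
  vals <- if (inherits(em, "expr_matrix")) em$values else em
  if (ncol(vals) < 2L) stop("need at least two samples to cluster")
  stats::hclust(stats::dist(t(vals), method = "euclidean"), method = linkage)
}

#' Clades (internal-node member sets) of a sample dendrogram
#'
#' @param hc An `hclust` object.
#' @return Named list: for each internal node, the sorted character vector
#'   of leaf labels below it. Names are canonical `|`-joined keys so clades
#'   can be matched by member-set identity across trees.
#' @export
dendrogram_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    members[[i]] <- sort(c(
      if (m[1] < 0) hc$labels[-m[1]] else members[[m[1]]],
      if (m[2] < 0) hc$labels[-m[2]] else members[[m[2]]]
    ))
  }
  names(members) <- vapply(members, paste, "", collapse = "|")
  members
}

#' Multiscale bootstrap support (BP and AU) for dendrogram clades
#'
#' Genes (rows) are resampled with replacement at several relative sizes
#' `r`; at each scale the sample dendrogram is recomputed and each original
#' clade's bootstrap probability `BP_r` is the fraction of resamples whose
#' tree contains the clade as a member set. `bp` is `BP` at `r = 1`. The
#' approximately unbiased p-value `au` comes from fitting the
#' signed-distance/curvature model
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` by weighted least squares
#' (binomial variance weights; boundary BP clipped by `1/(2 n_boot)`) and
#' evaluating `au = 1 - pnorm(v - c)`.
#'
#' @param em [expr_matrix] or matrix used to build `hc`.
#' @param hc `hclust` from [hcluster_samples()].
#' @param scales Relative resample sizes; must contain 1 and at least two
#'   distinct values. Default `seq(0.5, 1.4, by = 0.1)`.
#' @param n_boot Bootstrap replicates per scale (>= 100); default 1000.
#' @param seed Integer seed making the resampling deterministic.
#' @param linkage Linkage used for the bootstrap trees (same as `hc`).
#' @return data.frame, one row per internal node of `hc` (root included):
#'   `clade` (canonical key), `bp`, `au`, `flag` (`ok`, `degenerate_high`
#'   when observed in every resample at every scale, `degenerate_low` when
#'   never observed), plus one `bp_r_<r>` column per scale.
#' @export
multiscale_bootstrap_support <- function(em, hc,
                                         scales = seq(0.5, 1.4, by = 0.1),
                                         n_boot = 1000, seed = 1,
                                         linkage = "average") {
  vals <- if (inherits(em, "expr_matrix")) em$values else em
  scales <- round(scales, 10)
  if (length(unique(scales)) < 2L)
    stop("AU fitting needs at least two distinct scales")
  if (!any(abs(scales - 1) < 1e-9)) stop("scales must include 1.0")
  if (n_boot < 100) stop("n_boot must be at least 100")
  clades <- dendrogram_clades(hc)
  keys <- names(clades)
  n_genes <- nrow(vals)
  counts <- matrix(0L, nrow = length(keys), ncol = length(scales),
                   dimnames = list(keys, paste0("r", scales)))
  set.seed(as.integer(seed))
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * n_genes))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_genes, m, replace = TRUE)
      hb <- stats::hclust(stats::dist(t(vals[idx, , drop = FALSE])),
                          method = linkage)
      bkeys <- names(dendrogram_clades(hb))
      hit <- keys %in% bkeys
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  bp_r <- counts / n_boot
  at_one <- which(abs(scales - 1) < 1e-9)[1L]
  fit <- t(vapply(seq_along(keys), function(i)
    au_fit(bp_r[i, ], scales, n_boot), numeric(2L)))
  out <- data.frame(clade = keys,
                    bp = bp_r[, at_one],
                    au = fit[, 1L],
                    flag = c("ok", "degenerate_high", "degenerate_low")[fit[, 2L] + 1L],
                    stringsAsFactors = FALSE)
  bp_cols <- as.data.frame(bp_r)
  colnames(bp_cols) <- paste0("bp_r_", scales)
  out <- cbind(out, bp_cols)
  rownames(out) <- NULL
  out
}

#' Fit the multiscale-bootstrap AU model to one clade's BP profile
#'
#' Exposed separately so constructed BP profiles can be fed to the fitting
#' step directly.
#'
#' @param bp Numeric vector of bootstrap probabilities, one per scale.
#' @param scales Relative resample sizes (same length).
#' @param n_boot Replicates per scale, for the binomial weights and the
#'   boundary clip.
#' @return Numeric vector `c(au, flag_code)` with flag code 0 = ok,
#'   1 = degenerate high (all BP = 1), 2 = degenerate low (all BP = 0).
#' @export
au_fit <- function(bp, scales, n_boot) {
  if (all(bp >= 1)) return(c(1, 1))
  if (all(bp <= 0)) return(c(0, 2))
  clip <- 1 / (2 * n_boot)
  bpc <- pmin(pmax(bp, clip), 1 - clip)
  z <- stats::qnorm(1 - bpc)
  w <- stats::dnorm(z)^2 * n_boot / (bpc * (1 - bpc))  # inverse variance
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  coef <- tryCatch(
    solve(crossprod(X, X * w), crossprod(X, z * w)),
    error = function(e) NULL)
  if (is.null(coef)) return(c(bp[which.min(abs(scales - 1))], 0))
  v <- coef[1L]; cc <- coef[2L]
  c(min(max(1 - stats::pnorm(v - cc), 0), 1), 0)
}
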