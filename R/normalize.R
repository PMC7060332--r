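#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution:
#' each column's sorted values are replaced by the across-column mean of
#' sorted values at each rank. A group of tied values within a column
#' receives the mean of the reference values at the sort positions the
#' group spans, so ties stay tied.
#'
#' @param em [expr_matrix] or numeric matrix, no missing values.
#' @return Same type as the input, quantile-normalized.
#' @export
quantile_normalize <- function(em) {
  vals <- if (inherits(em, "expr_matrix")) em$values else em
  if (anyNA(vals)) stop("missing values are not supported")
  if (ncol(vals) < 2L) {
    warning("single-column matrix returned unchanged")
    return(em)
  }
  ref <- rowMeans(apply(vals, 2L, sort))
  out <- apply(vals, 2L, function(col) {
    o <- order(col)
    res <- numeric(length(col))
    res[o] <- stats::ave(ref, match(col[o], unique(col[o])))
    res
  })
  dimnames(out) <- dimnames(vals)
  if (inherits(em, "expr_matrix")) with_values(em, out) else out
}

#' Per-gene one-way ANOVA screen across conditions
#'
#' Fixed-effects one-way F test of each gene's expression across the
#' condition groups (via \code{stats::oneway.test} with equal variances,
#' the classical ANOVA F). A gene is selected when its raw p-value is
#' strictly below `alpha`; no multiple-testing correction is applied.
#' Genes whose groups separate perfectly (zero within-group variance,
#' unequal means) are flagged `infinite_F` and selected with p = 0; genes
#' constant across all samples are flagged `constant` and skipped.
#'
#' @param em [expr_matrix], at least two conditions with two samples each.
#' @param alpha Selection threshold on the raw p-value; default 0.01.
#' @return A list with `table` (data.frame: gene, F, p, flag, one mean
#'   column per condition, `selected`) and `selected` (character vector of
#'   selected gene ids).
#' @export
anova_screen <- function(em, alpha = 0.01) {
  stopifnot(inherits(em, "expr_matrix"), alpha > 0, alpha < 1)
  grp <- factor(unname(em$condition), levels = unique(unname(em$condition)))
  if (nlevels(grp) < 2L) stop("ANOVA needs at least two conditions")
  if (any(table(grp) < 2L)) stop("every condition needs at least two samples")
  vals <- em$values
  eps <- 1e-12
  res <- t(vapply(seq_len(nrow(vals)), function(i) {
    y <- vals[i, ]
    gm <- tapply(y, grp, mean)
    ss_tot <- sum((y - mean(y))^2)
    ss_within <- sum((y - gm[grp])^2)
    if (ss_tot < eps) return(c(NA_real_, NA_real_, 1))   # constant
    if (ss_within < eps) return(c(Inf, 0, 2))            # perfect separation
    ft <- stats::oneway.test(y ~ grp, var.equal = TRUE)
    c(unname(ft$statistic), unname(ft$p.value), 0)
  }, numeric(3L)))
  flag <- c("ok", "constant", "infinite_F")[res[, 3L] + 1L]
  tab <- data.frame(gene_id = rownames(vals), F = res[, 1L], p = res[, 2L],
                    flag = flag, stringsAsFactors = FALSE)
  cm <- condition_means(em)
  colnames(cm) <- paste0("mean_", colnames(cm))
  tab <- cbind(tab, as.data.frame(cm))
  tab$selected <- !is.na(tab$p) & tab$p < alpha
  rownames(tab) <- NULL
  list(table = tab, selected = tab$gene_id[tab$selected])
}

#' Z-score matrix rows
#'
#' Each row is centred by its mean and scaled by its population standard
#' deviation (divisor n), the convention used for expression heatmaps.
#'
#' @param em [expr_matrix] or numeric matrix; rows must be non-constant.
#' @return Same type, rows with mean 0 and population SD 1.
#' @export
zscore_rows <- function(em) {
  vals <- if (inherits(em, "expr_matrix")) em$values else em
  mu <- rowMeans(vals)
  sd_pop <- sqrt(rowMeans((vals - mu)^2))
  if (any(sd_pop == 0))
    stop("constant row cannot be z-scored: ",
         rownames(vals)[which(sd_pop == 0)[1]])
  out <- (vals - mu) / sd_pop
  if (inherits(em, "expr_matrix")) with_values(em, out) else out
}

#' Per-gene fold changes between condition pairs
#'
#' Fold change is computed on per-condition means of log2 values:
#' `fc = 2^(mean_A - mean_B)`, labelled `up` when fc > 2, `down` when
#' fc < 0.5, `neither` otherwise (both strict).
#'
#' @param em [expr_matrix] of log2 values.
#' @param comparisons List of `c(A, B)` condition-name pairs; default the
#'   three comparisons of the injury/treatment design (see
#'   [default_comparisons()]).
#' @param fc_up,fc_down Strict thresholds; defaults 2 and 0.5.
#' @return data.frame with columns `gene_id`, `comparison` ("A_vs_B"),
#'   `fc`, `label`.
#' @export
group_fold_change <- function(em, comparisons = default_comparisons(),
                              fc_up = 2.0, fc_down = 0.5) {
  stopifnot(inherits(em, "expr_matrix"))
  cm <- condition_means(em)
  rows <- lapply(comparisons, function(cp) {
    a <- cp[[1L]]; b <- cp[[2L]]
    if (!all(c(a, b) %in% colnames(cm)))
      stop("unknown condition in comparison: ", a, " vs ", b)
    fc <- 2^(cm[, a] - cm[, b])
    data.frame(gene_id = rownames(cm),
               comparison = paste0(a, "_vs_", b),
               fc = fc,
               label = ifelse(fc > fc_up, "up",
                              ifelse(fc < fc_down, "down", "neither")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The design's three condition comparisons
#'
#' Injury effect (NMDA-saline vs non-treat) and the two treatment effects
#' (each KUS arm vs NMDA-saline).
#'
#' @param conditions Character vector of the four condition names in
#'   design order.
#' @return List of `c(A, B)` pairs.
#' @export
default_comparisons <- function(conditions = c("non-treat", "NMDA-saline",
                                               "KUS121", "KUS187")) {
  list(c(conditions[2L], conditions[1L]),
       c(conditions[3L], conditions[2L]),
       c(conditions[4L], conditions[2L]))
}

#' Split a fold-change table into named up/down gene lists
#'
#' @param fc_table Output of [group_fold_change()].
#' @return Named list of character vectors, names `up_A_vs_B` /
#'   `down_A_vs_B` per comparison.
#' @export
fold_change_gene_lists <- function(fc_table) {
  out <- list()
  for (cmp in unique(fc_table$comparison)) {
    sub <- fc_table[fc_table$comparison == cmp, ]
    out[[paste0("up_", cmp)]] <- sub$gene_id[sub$label == "up"]
    out[[paste0("down_", cmp)]] <- sub$gene_id[sub$label == "down"]
  }
  out
}
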