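#' Filter read pairs for validity
#'
#' A fragment is kept when both mates are mapped, on the same chromosome,
#' oriented oppositely (one `+`, one `-`), and the distance between the
#' mates' leftmost positions is strictly below `max_distance`. Each
#' rejected pair is charged to the first failing reason in the fixed order
#' unmapped, different_chromosome, same_orientation, too_far.
#'
#' @param pairs `data.frame` from [read_sam_pairs()].
#' @param max_distance Maximum allowed mate distance in bp (exclusive);
#'   default 500000.
#' @return A list with `valid` (the retained rows of `pairs`) and `stats`,
#'   a list with `total_pairs`, `valid_pairs`, `rejected_by_reason`
#'   (named integer vector), `fraction_valid`, and `mapped_read_total`
#'   (count of mapped mates, the library-size denominator: a half-mapped
#'   pair still contributes its mapped mate).
#' @export
filter_pairs <- function(pairs, max_distance = 500000) {
  stopifnot(max_distance > 0)
  n <- nrow(pairs)
  reasons <- c("unmapped", "different_chromosome", "same_orientation", "too_far")
  if (n == 0L) {
    stats <- list(total_pairs = 0L, valid_pairs = 0L,
                  rejected_by_reason = stats::setNames(integer(4L), reasons),
                  fraction_valid = 0,
                  mapped_read_total = 0L)
    return(list(valid = pairs, stats = stats))
  }
  unmapped <- !pairs$mapped
  diff_chrom <- !unmapped & pairs$chrom1 != pairs$chrom2
  same_orient <- !unmapped & !diff_chrom & pairs$strand1 == pairs$strand2
  too_far <- !unmapped & !diff_chrom & !same_orient &
    abs(pairs$pos2 - pairs$pos1) >= max_distance
  valid <- !(unmapped | diff_chrom | same_orient | too_far)
  rejected <- stats::setNames(
    c(sum(unmapped), sum(diff_chrom), sum(same_orient), sum(too_far)), reasons)
  stats <- list(
    total_pairs = n,
    valid_pairs = sum(valid),
    rejected_by_reason = rejected,
    fraction_valid = sum(valid) / n,
    mapped_read_total = sum(pairs$mapped1) + sum(pairs$mapped2)
  )
  list(valid = pairs[valid, , drop = FALSE], stats = stats)
}

#' Count valid pairs over terminal exons (one sample)
#'
#' A pair increments a gene when the leftmost aligned position of either
#' mate lies inside the gene's terminal exon (1-based inclusive). The pair
#' is the counting unit: both mates in the same exon count once. A pair
#' whose mates hit terminal exons of two genes increments both.
#'
#' @param valid_pairs `data.frame` of filtered pairs ([filter_pairs()]).
#' @param models Gene models from [read_gene_models()].
#' @return Named integer vector of counts, one entry per gene in `models`.
#' @export
count_terminal_exons <- function(valid_pairs, models) {
  counts <- stats::setNames(integer(nrow(models)), models$gene_id)
  if (!nrow(valid_pairs)) return(counts)
  term <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(models$terminal_start, models$terminal_end))
  hit_tab <- lapply(1:2, function(mate) {
    chrom <- valid_pairs[[paste0("chrom", mate)]]
    pos <- valid_pairs[[paste0("pos", mate)]]
    pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    ov <- GenomicRanges::findOverlaps(pts, term)
    cbind(pair = S4Vectors::queryHits(ov), gene = S4Vectors::subjectHits(ov))
  })
  hits <- unique(do.call(rbind, hit_tab))
  if (nrow(hits)) {
    tab <- table(factor(hits[, "gene"], levels = seq_len(nrow(models))))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Assemble a count matrix from per-sample SAM files
#'
#' Runs [read_sam_pairs()], [filter_pairs()] and [count_terminal_exons()]
#' per sample.
#'
#' @param sam_paths Named character vector: sample id -> SAM path.
#' @param models Gene models from [read_gene_models()].
#' @param max_distance Passed to [filter_pairs()].
#' @return A list with `counts` (genes x samples integer matrix),
#'   `mapped_read_total` (named integer vector per sample) and
#'   `filter_stats` (per-sample list from [filter_pairs()]).
#' @export
quantify_samples <- function(sam_paths, models, max_distance = 500000) {
  stopifnot(!is.null(names(sam_paths)), all(nzchar(names(sam_paths))))
  per_sample <- lapply(sam_paths, function(p) {
    flt <- filter_pairs(read_sam_pairs(p), max_distance = max_distance)
    list(counts = count_terminal_exons(flt$valid, models), stats = flt$stats)
  })
  counts <- vapply(per_sample, `[[`, integer(nrow(models)), "counts")
  if (nrow(models) == 1L)
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(models$gene_id, names(sam_paths)))
  list(
    counts = counts,
    mapped_read_total = vapply(per_sample,
                               function(s) as.integer(s$stats$mapped_read_total),
                               integer(1L)),
    filter_stats = lapply(per_sample, `[[`, "stats")
  )
}

#' Reads Per Kilobase of exon model per 10 Million mapped reads
#'
#' `RPK10M(g, s) = count(g, s) / (L_g / 1000) / (M_s / 1e7)` with `L_g`
#' the gene's terminal-exon length in bp and `M_s` the sample's mapped-read
#' total.
#'
#' @param counts Genes x samples integer matrix.
#' @param models Gene models from [read_gene_models()] (provides
#'   `terminal_length` per gene, matched by rowname).
#' @param mapped_read_total Named numeric vector of mapped reads per sample.
#' @return Genes x samples numeric matrix of linear-scale RPK10M.
#' @export
compute_rpk10m <- function(counts, models, mapped_read_total) {
  lens <- models$terminal_length[match(rownames(counts), models$gene_id)]
  if (anyNA(lens)) stop("count matrix row without a gene model")
  if (any(lens <= 0)) stop("non-positive terminal exon length")
  mt <- mapped_read_total[colnames(counts)]
  if (anyNA(mt)) stop("sample without mapped_read_total")
  if (any(mt <= 0))
    stop("sample with zero mapped reads: ",
         colnames(counts)[which(mt <= 0)[1]])
  sweep(counts / (lens / 1000), 2L, mt / 1e7, "/")
}

#' Log2-transform a non-negative matrix with a pseudocount
#'
#' @param m Numeric matrix with values >= 0.
#' @param pseudocount Added before taking log2; default 1.
#' @return `log2(m + pseudocount)`.
#' @export
log_transform <- function(m, pseudocount = 1.0) {
  vals <- if (inherits(m, "expr_matrix")) m$values else m
  if (any(vals < 0)) stop("negative values cannot be log-transformed")
  out <- log2(vals + pseudocount)
  if (inherits(m, "expr_matrix")) with_values(m, out) else out
}

#' Keep genes expressed above a log2 threshold
#'
#' A gene is expressed when the maximum of its per-condition mean log2
#' values exceeds `threshold` strictly.
#'
#' @param em [expr_matrix] of log2 values.
#' @param threshold Strict lower bound on the per-condition mean maximum;
#'   default 3.
#' @return An [expr_matrix] restricted to the expressed genes (possibly
#'   zero rows); samples unchanged.
#' @export
filter_expressed <- function(em, threshold = 3.0) {
  stopifnot(inherits(em, "expr_matrix"))
  cm <- condition_means(em)
  keep <- apply(cm, 1L, max) > threshold
  with_values(em, em$values[keep, , drop = FALSE])
}

#' Expression ratios relative to a reference gene and baseline timepoint
#'
#' `ratio(t) = (target(t) / reference(t)) / (target(t0) / reference(t0))`,
#' the normalization used for actin-relative time-course comparisons; the
#' baseline timepoint maps to 1 by construction.
#'
#' @param target Numeric vector of target-gene values per timepoint.
#' @param reference Numeric vector of reference-gene (e.g. actin) values,
#'   same length; must be positive.
#' @param baseline Index (or name) of the baseline timepoint; default 1.
#' @return Numeric vector of ratios, same names as `target`.
#' @export
relative_expression_ratio <- function(target, reference, baseline = 1L) {
  if (length(target) != length(reference))
    stop("target and reference must have the same length")
  if (any(reference <= 0)) stop("reference values must be positive")
  rel <- target / reference
  if (rel[baseline] <= 0) stop("baseline ratio must be positive")
  rel / rel[[baseline]]
}
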