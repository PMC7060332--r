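#' Synthetic study design
#'
#' Parameters of the synthetic four-condition experiment the generator
#' emulates: three replicates per condition, genes planted with the
#' hyper-cluster-A pattern (up after injury, restored down by both KUS
#' arms), the hyper-cluster-B pattern (up, then further up), or no effect,
#' plus a configurable fraction of invalid read pairs. The default
#' invalid-pair fractions sum to 0.389 so that about 61.1% of pairs
#' survive the validity filter, the usable fraction typical of this
#' library preparation.
#'
#' @param n_genes Number of genes; default 2000.
#' @param conditions The four condition names, in design order.
#' @param replicates Replicates per condition (>= 2); default 3.
#' @param frac_hyperA,frac_hyperB Proportions of planted pattern genes;
#'   defaults 0.03 and 0.0075.
#' @param effect_log2 Planted between-condition shift (log2 units);
#'   default 1.
#' @param noise_sd_log2 Replicate noise SD in log2 space; default 0.25.
#' @param invalid_pair_fracs Named numeric vector with entries
#'   `interchromosomal`, `same_orientation`, `too_far`.
#' @param library_size Read pairs per sample; default 3e5, a desk-scale
#'   stand-in for the tens of millions of pairs of a real library.
#' @param seed Integer master seed.
#' @return Validated list of class `sim_design`.
#' @export
sim_design <- function(n_genes = 2000,
                       conditions = c("non-treat", "NMDA-saline",
                                      "KUS121", "KUS187"),
                       replicates = 3,
                       frac_hyperA = 0.03, frac_hyperB = 0.0075,
                       effect_log2 = 1, noise_sd_log2 = 0.25,
                       invalid_pair_fracs = c(interchromosomal = 0.15,
                                              same_orientation = 0.10,
                                              too_far = 0.139),
                       library_size = 3e5, seed = 1) {
  stopifnot(n_genes >= 1, replicates >= 2, library_size > 0,
            effect_log2 >= 0, noise_sd_log2 >= 0)
  if (frac_hyperA < 0 || frac_hyperB < 0 || frac_hyperA + frac_hyperB > 1)
    stop("class fractions must be in [0,1] and sum to at most 1")
  need <- c("interchromosomal", "same_orientation", "too_far")
  if (!all(need %in% names(invalid_pair_fracs)))
    stop("invalid_pair_fracs needs entries: ", paste(need, collapse = ", "))
  invalid_pair_fracs <- invalid_pair_fracs[need]
  if (any(invalid_pair_fracs < 0) || sum(invalid_pair_fracs) >= 1)
    stop("invalid_pair_fracs must be non-negative and sum below 1")
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 replicates = as.integer(replicates),
                 frac_hyperA = frac_hyperA, frac_hyperB = frac_hyperB,
                 effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
                 invalid_pair_fracs = invalid_pair_fracs,
                 library_size = as.integer(library_size),
                 seed = as.integer(seed)),
            class = "sim_design")
}

sample_ids <- function(design) {
  unlist(lapply(design$conditions, function(cc)
    paste0(gsub("[^A-Za-z0-9]", "", cc), "_rep", seq_len(design$replicates))))
}

sample_conditions <- function(design) {
  stats::setNames(rep(design$conditions, each = design$replicates),
                  sample_ids(design))
}

#' Simulate a gene annotation
#'
#' Non-overlapping genes on at least two chromosomes, 1-4 exons each,
#' mixed strands; terminal-exon lengths drawn uniformly in 200-2000 bp,
#' internal exons 100-300 bp. Byte-deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param gtf_path Optional path; when given the annotation is also
#'   written as GTF exon features.
#' @return Gene-model data.frame in the layout of [read_gene_models()],
#'   with chromosome lengths attached as attribute `chrom_lengths`.
#' @export
simulate_annotation <- function(n_genes, seed = 1, gtf_path = NULL) {
  stopifnot(n_genes >= 1)
  set.seed(as.integer(seed))
  n_chrom <- max(2L, ceiling(n_genes / 500))
  chroms <- paste0("chr", seq_len(n_chrom))
  cursor <- stats::setNames(rep(1000L, n_chrom), chroms)
  rows <- vector("list", n_genes)
  gtf <- character(0)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("g%05d", i)
    chrom <- chroms[(i - 1L) %% n_chrom + 1L]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(1:4, 1L)
    lens <- sample(100:300, n_ex, replace = TRUE)
    term_idx <- if (strand == "+") n_ex else 1L
    lens[term_idx] <- sample(200:2000, 1L)
    gaps <- if (n_ex > 1L) sample(100:2000, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor[[chrom]]
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + lens[e] - 1L
      pos <- ends[e] + (if (e < n_ex) gaps[e] else 0L) + 1L
    }
    cursor[[chrom]] <- ends[n_ex] + sample(500:5000, 1L)
    rows[[i]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand, n_exons = n_ex,
      terminal_start = starts[term_idx], terminal_end = ends[term_idx],
      terminal_length = lens[term_idx],
      exons = I(list(cbind(start = starts, end = ends))),
      stringsAsFactors = FALSE)
    if (!is.null(gtf_path))
      gtf <- c(gtf, sprintf(
        "%s\trgcflow_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
        chrom, starts, ends, strand, gid, gid))
  }
  models <- do.call(rbind, rows)
  rownames(models) <- models$gene_id
  attr(models, "chrom_lengths") <- stats::setNames(
    pmax(cursor + 700000L, 1000000L), chroms)
  if (!is.null(gtf_path)) writeLines(gtf, gtf_path)
  models
}

#' Simulate the truth table of planted expression patterns
#'
#' Gene classes are drawn from the design's fractions; per-condition true
#' mean log2 expression satisfies the defining inequalities exactly:
#' hyperA genes rise by `effect_log2` after injury and fall back under
#' both treatments, hyperB genes rise and rise again, null genes are flat.
#'
#' @param design A [sim_design()].
#' @return data.frame: `gene_id`, `class`, one `mean_<condition>` column
#'   per condition.
#' @export
simulate_truth <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed + 1L)
  n <- design$n_genes
  cls <- sample(c("hyperA", "hyperB", "null"), n, replace = TRUE,
                prob = c(design$frac_hyperA, design$frac_hyperB,
                         1 - design$frac_hyperA - design$frac_hyperB))
  b <- stats::runif(n, 5, 9)
  e <- design$effect_log2
  mu <- cbind(b,
              b + ifelse(cls == "null", 0, e),
              b + ifelse(cls == "hyperB", 2 * e, 0),
              b + ifelse(cls == "hyperB", 2 * e, 0))
  colnames(mu) <- paste0("mean_", design$conditions)
  out <- data.frame(gene_id = sprintf("g%05d", seq_len(n)), class = cls,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mu))
}

#' Simulate per-sample paired alignments
#'
#' Valid fragments are placed inside each gene's terminal exon in FR
#' orientation (leftmost mate on `+`), with per-gene Poisson counts whose
#' expectations are proportional to `2^(true mean + replicate noise)`
#' times terminal-exon length, scaled so valid plus injected invalid
#' pairs meet the design's library size. Invalid pairs are injected with
#' exactly one defect each (interchromosomal, same orientation, or mates
#' >= 500 kb apart) and recorded in a manifest.
#'
#' @param truth [simulate_truth()] output.
#' @param models [simulate_annotation()] output covering the truth genes.
#' @param design The [sim_design()].
#' @param dir Output directory for one SAM per sample.
#' @return List: `sam_paths` (named by sample), `manifest` (data.frame
#'   sample, pair_id, defect), `design_path`-ready condition map under
#'   `condition`.
#' @export
simulate_alignments <- function(truth, models, design, dir) {
  stopifnot(inherits(design, "sim_design"))
  if (!all(truth$gene_id %in% models$gene_id))
    stop("models do not cover all truth genes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(design$seed + 2L)
  chrom_lengths <- attr(models, "chrom_lengths")
  if (is.null(chrom_lengths))
    chrom_lengths <- stats::setNames(
      vapply(split(models$terminal_end, models$chrom), max, 0) + 700000,
      names(split(models$terminal_end, models$chrom)))
  chroms <- names(chrom_lengths)
  cond_map <- sample_conditions(design)
  mo <- models[match(truth$gene_id, models$gene_id), ]
  n_inv <- round(design$invalid_pair_fracs * design$library_size)
  n_valid_target <- design$library_size - sum(n_inv)
  manifests <- list(); sam_paths <- character(0)
  for (s in names(cond_map)) {
    mu <- truth[[paste0("mean_", cond_map[[s]])]]
    w <- 2^(mu + stats::rnorm(nrow(truth), 0, design$noise_sd_log2)) *
      mo$terminal_length
    counts <- stats::rpois(nrow(truth), n_valid_target * w / sum(w))
    gi <- rep.int(seq_len(nrow(truth)), counts)
    nv <- length(gi)
    L <- mo$terminal_length[gi]
    p1 <- mo$terminal_start[gi] + floor(stats::runif(nv) * (L - 1L))
    room <- mo$terminal_end[gi] - p1
    gap <- 1L + floor(stats::runif(nv) * pmin(room, 300L))
    valid <- data.frame(
      pair_id = sprintf("%s_v%06d", s, seq_len(nv)),
      chrom1 = mo$chrom[gi], pos1 = as.integer(p1), strand1 = "+",
      mapped1 = TRUE,
      chrom2 = mo$chrom[gi], pos2 = as.integer(p1 + gap), strand2 = "-",
      mapped2 = TRUE, stringsAsFactors = FALSE)
    inv <- list()
    if (n_inv[["interchromosomal"]] > 0) {
      m <- n_inv[["interchromosomal"]]
      c1 <- sample(chroms, m, replace = TRUE)
      c2 <- chroms[(match(c1, chroms) %% length(chroms)) + 1L]
      inv$interchromosomal <- data.frame(
        pair_id = sprintf("%s_ic%06d", s, seq_len(m)),
        chrom1 = c1, pos1 = sample(1000:200000, m, replace = TRUE),
        strand1 = "+", mapped1 = TRUE,
        chrom2 = c2, pos2 = sample(1000:200000, m, replace = TRUE),
        strand2 = "-", mapped2 = TRUE, stringsAsFactors = FALSE)
    }
    if (n_inv[["same_orientation"]] > 0) {
      m <- n_inv[["same_orientation"]]
      c1 <- sample(chroms, m, replace = TRUE)
      pos <- sample(1000:200000, m, replace = TRUE)
      inv$same_orientation <- data.frame(
        pair_id = sprintf("%s_so%06d", s, seq_len(m)),
        chrom1 = c1, pos1 = pos, strand1 = "+", mapped1 = TRUE,
        chrom2 = c1, pos2 = pos + 200L, strand2 = "+", mapped2 = TRUE,
        stringsAsFactors = FALSE)
    }
    if (n_inv[["too_far"]] > 0) {
      m <- n_inv[["too_far"]]
      c1 <- sample(chroms, m, replace = TRUE)
      pos <- sample(1:1000, m, replace = TRUE)
      inv$too_far <- data.frame(
        pair_id = sprintf("%s_tf%06d", s, seq_len(m)),
        chrom1 = c1, pos1 = pos, strand1 = "+", mapped1 = TRUE,
        chrom2 = c1, pos2 = pos + 500000L + sample(0:50000, m, replace = TRUE),
        strand2 = "-", mapped2 = TRUE, stringsAsFactors = FALSE)
    }
    pairs <- rbind(valid, do.call(rbind, unname(inv)))
    pairs$mapped <- pairs$mapped1 & pairs$mapped2
    path <- file.path(dir, paste0(s, ".sam"))
    write_sam_pairs(pairs, chrom_lengths, path)
    sam_paths[s] <- path
    manifests[[s]] <- if (length(inv)) {
      do.call(rbind, lapply(names(inv), function(d)
        data.frame(sample = s, pair_id = inv[[d]]$pair_id, defect = d,
                   stringsAsFactors = FALSE)))
    } else {
      data.frame(sample = character(), pair_id = character(),
                 defect = character(), stringsAsFactors = FALSE)
    }
  }
  list(sam_paths = sam_paths,
       manifest = do.call(rbind, unname(manifests)),
       condition = cond_map)
}

#' Simulate gene sets with one planted enriched set
#'
#' One set (`PLANTED`) contains `planted_overlap` hyperA genes plus random
#' fillers; the remaining sets are drawn uniformly from all genes.
#'
#' @param truth [simulate_truth()] output.
#' @param n_sets Total number of sets; default 50.
#' @param planted_set_size Size of the planted set; default 20.
#' @param planted_overlap HyperA genes inside the planted set; default 10.
#' @param seed Integer seed.
#' @param gmt_path Optional path; when given the sets are written as GMT.
#' @return Named list of gene sets with attribute `planted = "PLANTED"`.
#' @export
simulate_genesets <- function(truth, n_sets = 50, planted_set_size = 20,
                              planted_overlap = 10, seed = 1,
                              gmt_path = NULL) {
  hyperA <- truth$gene_id[truth$class == "hyperA"]
  if (planted_overlap > planted_set_size)
    stop("planted_overlap exceeds planted_set_size")
  if (planted_overlap > length(hyperA))
    stop("planted_overlap exceeds the number of hyperA genes (",
         length(hyperA), ")")
  set.seed(as.integer(seed))
  fillers <- setdiff(truth$gene_id, hyperA)
  planted <- c(sample(hyperA, planted_overlap),
               sample(fillers, planted_set_size - planted_overlap))
  sets <- c(list(PLANTED = structure(planted,
                                     description = "planted hyperA set")),
            stats::setNames(lapply(seq_len(n_sets - 1L), function(i)
              structure(sample(truth$gene_id, planted_set_size),
                        description = sprintf("random set %d", i))),
              sprintf("RAND%03d", seq_len(n_sets - 1L))))
  if (!is.null(gmt_path)) write_gmt(sets, gmt_path)
  attr(sets, "planted") <- "PLANTED"
  sets
}

#' Generate the full synthetic input bundle
#'
#' Writes GTF annotation, one SAM per sample, the truth table, the
#' invalid-pair manifest, the design table and a GMT of gene sets into
#' `dir`.
#'
#' @param design A [sim_design()].
#' @param dir Output directory.
#' @param n_sets,planted_set_size,planted_overlap Passed to
#'   [simulate_genesets()].
#' @return List with `models`, `truth`, `sets`, `sam_paths`, `manifest`,
#'   `condition`, and the file paths (`gtf`, `gmt`, `truth_tsv`,
#'   `manifest_tsv`, `design_tsv`).
#' @export
simulate_inputs <- function(design, dir, n_sets = 50, planted_set_size = 20,
                            planted_overlap = 10) {
  stopifnot(inherits(design, "sim_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "annotation.gtf")
  models <- simulate_annotation(design$n_genes, seed = design$seed,
                                gtf_path = gtf)
  truth <- simulate_truth(design)
  aln <- simulate_alignments(truth, models, design,
                             file.path(dir, "alignments"))
  gmt <- file.path(dir, "genesets.gmt")
  overlap <- min(planted_overlap, sum(truth$class == "hyperA"))
  sets <- simulate_genesets(truth, n_sets = n_sets,
                            planted_set_size = planted_set_size,
                            planted_overlap = overlap,
                            seed = design$seed + 3L, gmt_path = gmt)
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest_tsv <- file.path(dir, "manifest.tsv")
  utils::write.table(aln$manifest, manifest_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  design_tsv <- file.path(dir, "design.tsv")
  utils::write.table(
    data.frame(sample_id = names(aln$condition),
               condition = unname(aln$condition)),
    design_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(models = models, truth = truth, sets = sets,
       sam_paths = aln$sam_paths, manifest = aln$manifest,
       condition = aln$condition, gtf = gtf, gmt = gmt,
       truth_tsv = truth_tsv, manifest_tsv = manifest_tsv,
       design_tsv = design_tsv)
}
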