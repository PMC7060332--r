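# in-code fixtures shared across test files

sam_line <- function(qname, flag, rname, pos, rnext = "=", pnext = 1) {
  sprintf("%s\t%d\t%s\t%d\t60\t50M\t%s\t%d\t0\t*\t*",
          qname, flag, rname, pos, rnext, pnext)
}

# header + a configurable set of records
write_sam_fixture <- function(lines, chroms = c(chr1 = 1000000L, chr2 = 1000000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms),
               lines), path)
  path
}

# a proper FR pair: mate1 +, mate2 -
proper_pair_lines <- function(id, chrom, pos1, pos2) {
  c(sam_line(id, 97L, chrom, pos1, "=", pos2),
    sam_line(id, 145L, chrom, pos2, "=", pos1))
}

# minimal gene-model table in the read_gene_models() layout
make_models <- function(gene_id, chrom, strand, terminal_start, terminal_end) {
  data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    n_exons = 1L,
    terminal_start = terminal_start, terminal_end = terminal_end,
    terminal_length = terminal_end - terminal_start + 1L,
    exons = I(mapply(function(s, e) cbind(start = s, end = e),
                     terminal_start, terminal_end, SIMPLIFY = FALSE)),
    stringsAsFactors = FALSE, row.names = gene_id)
}

# pairs data.frame in the read_sam_pairs() layout
make_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                       mapped1 = TRUE, mapped2 = TRUE) {
  n <- length(pos1)
  mapped1 <- rep_len(mapped1, n); mapped2 <- rep_len(mapped2, n)
  data.frame(pair_id = sprintf("p%03d", seq_len(n)),
             chrom1 = chrom1, pos1 = as.integer(pos1), strand1 = strand1,
             mapped1 = mapped1,
             chrom2 = chrom2, pos2 = as.integer(pos2), strand2 = strand2,
             mapped2 = mapped2,
             mapped = mapped1 & mapped2,
             stringsAsFactors = FALSE)
}

# small labelled matrix with the four-condition, three-replicate design
make_em <- function(values, n_rep = 3,
                    conditions = c("non-treat", "NMDA-saline", "KUS121", "KUS187")) {
  samples <- paste0(rep(conditions, each = n_rep), "_r", seq_len(n_rep))
  colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  expr_matrix(values, setNames(rep(conditions, each = n_rep), samples))
}

# condition-structured sample matrix: per-condition gene centers plus
# replicate noise, so replicates of a condition cluster together
make_grouped_samples <- function(n_genes = 60, sep = 6, sd = 0.3,
                                 n_cond = 4, n_rep = 3, seed = 21) {
  set.seed(seed)
  centers <- matrix(rnorm(n_genes * n_cond, sd = sep), n_genes, n_cond)
  vals <- centers[, rep(seq_len(n_cond), each = n_rep)] +
    rnorm(n_genes * n_cond * n_rep, sd = sd)
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  make_em(vals, n_rep = n_rep)
}

# independent sort-average quantile normalization oracle: each column's
# sorted values take the across-column mean at their rank; a tie group
# takes the mean of the reference values at the sort positions it occupies
quantile_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    o <- order(col)
    grp <- match(col[o], unique(col[o]))
    res <- numeric(length(col))
    for (g in unique(grp)) {
      at <- which(grp == g)
      res[o[at]] <- mean(ref[at])
    }
    res
  })
  dimnames(out) <- dimnames(m)
  out
}

# textbook sums-of-squares one-way ANOVA oracle
anova_oracle <- function(y, grp) {
  grp <- factor(grp)
  k <- nlevels(grp); n <- length(y)
  gm <- tapply(y, grp, mean); ns <- tapply(y, grp, length)
  ssb <- sum(ns * (gm - mean(y))^2)
  ssw <- sum((y - gm[grp])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# well-separated spherical Gaussian clusters on distinct axes
planted_gaussians <- function(k, n_per = 125, d = 12, sep = 5, sd = 1,
                              seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, d)
  for (i in seq_len(k)) centers[i, i] <- sep * i
  x <- centers[rep(seq_len(k), each = n_per), ] +
    matrix(rnorm(k * n_per * d, sd = sd), k * n_per, d)
  rownames(x) <- sprintf("p%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(d))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

# exhaustive oracle: global k-means for k = 1..k_max scored by the same
# spherical-Gaussian BIC, repeated restarts
exhaustive_bic_k <- function(x, k_max = 10, seed = 99) {
  set.seed(seed)
  best_k <- 1; best_bic <- -Inf
  for (k in seq_len(k_max)) {
    asg <- if (k == 1) rep(1L, nrow(x)) else
      kmeans(x, k, nstart = 10, iter.max = 50)$cluster
    b <- region_bic(x, asg)
    if (b > best_bic) { best_bic <- b; best_k <- k }
  }
  best_k
}

# exhaustive hypergeometric tail oracle: enumerate all C(N, n) draws
hyper_oracle <- function(k, n, K, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}
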