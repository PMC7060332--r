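#' Read gene models from a GTF file
#'
#' Imports `exon` features, groups them per gene, and designates the
#' terminal exon: the 3'-most exon in gene orientation (last exon in
#' coordinate order on `+`, first on `-`). When a gene carries several
#' transcripts, the transcript with the longest terminal exon is used and
#' its exon chain becomes the gene model, so exons within a model never
#' overlap.
#'
#' @param path Path to a GTF file with `exon` features carrying `gene_id`
#'   (and optionally `transcript_id`) attributes.
#' @param terminal Which end of the gene carries the counting exon;
#'   `"3prime"` (default) or `"5prime"`.
#' @return A `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `n_exons`, `terminal_start`, `terminal_end`,
#'   `terminal_length`, and a list-column `exons` of two-column matrices
#'   (start, end; 1-based inclusive).
#' @export
read_gene_models <- function(path, terminal = c("3prime", "5prime")) {
  terminal <- match.arg(terminal)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon feature without gene_id in ", path)
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    transcript_id = if (is.null(gr$transcript_id)) as.character(gr$gene_id)
                    else as.character(gr$transcript_id),
    stringsAsFactors = FALSE
  )
  if (any(df$end < df$start))
    stop("exon with end < start for gene ",
         df$gene_id[which(df$end < df$start)[1]])
  if (any(!df$strand %in% c("+", "-")))
    stop("exon with missing strand for gene ",
         df$gene_id[which(!df$strand %in% c("+", "-"))[1]])
  split_genes <- split(df, df$gene_id)
  models <- lapply(split_genes, function(g) {
    if (length(unique(g$chrom)) != 1L)
      stop("gene ", g$gene_id[1], " spans multiple chromosomes")
    if (length(unique(g$strand)) != 1L)
      stop("gene ", g$gene_id[1], " has inconsistent strand")
    # pick the transcript whose terminal exon is longest
    per_tx <- lapply(split(g, g$transcript_id), function(tx) {
      tx <- tx[order(tx$start), , drop = FALSE]
      term <- terminal_exon_row(tx, terminal)
      list(tx = tx, term = term,
           len = tx$end[term] - tx$start[term] + 1L)
    })
    best <- per_tx[[which.max(vapply(per_tx, `[[`, 0L, "len"))]]
    tx <- best$tx
    if (nrow(tx) > 1L && any(tx$start[-1L] <= tx$end[-nrow(tx)]))
      stop("overlapping exons within gene ", g$gene_id[1])
    ti <- best$term
    data.frame(
      gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
      n_exons = nrow(tx),
      terminal_start = tx$start[ti], terminal_end = tx$end[ti],
      terminal_length = tx$end[ti] - tx$start[ti] + 1L,
      exons = I(list(cbind(start = tx$start, end = tx$end))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, models)
  rownames(out) <- out$gene_id
  out
}

# row index of the terminal exon in a coordinate-sorted exon table
terminal_exon_row <- function(tx, terminal) {
  three_prime_last <- tx$strand[1] == "+"
  want_last <- if (terminal == "3prime") three_prime_last else !three_prime_last
  if (want_last) nrow(tx) else 1L
}
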