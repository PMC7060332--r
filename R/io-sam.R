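SAM_FLAG_PAIRED <- 0x1L
SAM_FLAG_UNMAPPED <- 0x4L
SAM_FLAG_MATE_UNMAPPED <- 0x8L
SAM_FLAG_REVERSE <- 0x10L
SAM_FLAG_MATE_REVERSE <- 0x20L
SAM_FLAG_FIRST <- 0x40L
SAM_FLAG_SECOND <- 0x80L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read paired-end alignments from a SAM file
#'
#' Parses the eleven mandatory SAM fields and joins mates by query name
#' into one record per fragment. Records whose mate never appears in the
#' file (orphans) are counted and dropped, not emitted. Pairs are emitted
#' in file order of their first-seen mate.
#'
#' @param path Path to a SAM file (plain text, `@`-prefixed header lines
#'   allowed).
#' @return A `data.frame` with one row per read pair and columns
#'   `pair_id`, `chrom1`, `pos1`, `strand1`, `mapped1`, `chrom2`, `pos2`,
#'   `strand2`, `mapped2`, and `mapped` (both mates mapped). The number of
#'   orphan records is attached as attribute `orphan_count`.
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
#'   "p1\t97\tchr1\t100\t60\t50M\t=\t400\t0\t*\t*",
#'   "p1\t145\tchr1\t400\t60\t50M\t=\t100\t0\t*\t*"), sam)
#' read_sam_pairs(sam)
#' @export
read_sam_pairs <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  if (any(is_header)) {
    hdr <- lines[is_header]
    bad <- which(!grepl("^@(HD|SQ|RG|PG|CO)(\t|$)", hdr))
    if (length(bad))
      stop("malformed SAM header at line ", which(is_header)[bad[1]])
  }
  body_idx <- which(!is_header & nzchar(lines))
  if (!length(body_idx)) {
    return(empty_pairs(orphans = 0L))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM record (fewer than 11 fields) at line ",
         body_idx[which(nf < 11L)[1]])
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  if (anyNA(flag) || anyNA(pos))
    stop("malformed SAM record (non-numeric FLAG or POS) at line ",
         body_idx[which(is.na(flag) | is.na(pos))[1]])

  unmapped <- has_flag(flag, SAM_FLAG_UNMAPPED)
  strand <- ifelse(has_flag(flag, SAM_FLAG_REVERSE), "-", "+")
  first <- has_flag(flag, SAM_FLAG_FIRST)

  cnt <- table(qname)
  paired_names <- names(cnt)[cnt == 2L]
  orphan_count <- sum(cnt != 2L)
  keep <- qname %in% paired_names
  if (!any(keep)) {
    return(empty_pairs(orphans = orphan_count))
  }
  qk <- qname[keep]
  ord <- order(match(qk, unique(qk)), !first[keep])
  idx <- which(keep)[ord]
  i1 <- idx[seq(1L, length(idx), by = 2L)]
  i2 <- idx[seq(2L, length(idx), by = 2L)]
  pairs <- data.frame(
    pair_id = qname[i1],
    chrom1 = rname[i1], pos1 = pos[i1], strand1 = strand[i1],
    mapped1 = !unmapped[i1],
    chrom2 = rname[i2], pos2 = pos[i2], strand2 = strand[i2],
    mapped2 = !unmapped[i2],
    stringsAsFactors = FALSE
  )
  pairs$mapped <- pairs$mapped1 & pairs$mapped2
  attr(pairs, "orphan_count") <- orphan_count
  pairs
}

empty_pairs <- function(orphans) {
  out <- data.frame(
    pair_id = character(), chrom1 = character(), pos1 = integer(),
    strand1 = character(), mapped1 = logical(), chrom2 = character(),
    pos2 = integer(), strand2 = character(), mapped2 = logical(),
    mapped = logical(), stringsAsFactors = FALSE
  )
  attr(out, "orphan_count") <- orphans
  out
}

#' Write read pairs to a SAM file
#'
#' Inverse of [read_sam_pairs()] for the minimal dialect this package
#' uses: two records per pair (mandatory fields only, `*` SEQ/QUAL,
#' fully-aligned 50M CIGAR), preceded by `@HD`/`@SQ` header lines.
#'
#' @param pairs `data.frame` as returned by [read_sam_pairs()].
#' @param chrom_lengths Named integer vector of chromosome lengths for the
#'   `@SQ` header lines.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam_pairs <- function(pairs, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  flag1 <- SAM_FLAG_PAIRED + SAM_FLAG_FIRST +
    ifelse(pairs$strand1 == "-", SAM_FLAG_REVERSE, 0L) +
    ifelse(pairs$strand2 == "-", SAM_FLAG_MATE_REVERSE, 0L) +
    ifelse(pairs$mapped1, 0L, SAM_FLAG_UNMAPPED) +
    ifelse(pairs$mapped2, 0L, SAM_FLAG_MATE_UNMAPPED)
  flag2 <- SAM_FLAG_PAIRED + SAM_FLAG_SECOND +
    ifelse(pairs$strand2 == "-", SAM_FLAG_REVERSE, 0L) +
    ifelse(pairs$strand1 == "-", SAM_FLAG_MATE_REVERSE, 0L) +
    ifelse(pairs$mapped2, 0L, SAM_FLAG_UNMAPPED) +
    ifelse(pairs$mapped1, 0L, SAM_FLAG_MATE_UNMAPPED)
  rnext1 <- ifelse(pairs$chrom2 == pairs$chrom1, "=", pairs$chrom2)
  rnext2 <- ifelse(pairs$chrom1 == pairs$chrom2, "=", pairs$chrom1)
  rec1 <- sprintf("%s\t%d\t%s\t%d\t60\t50M\t%s\t%d\t0\t*\t*",
                  pairs$pair_id, flag1, pairs$chrom1, pairs$pos1,
                  rnext1, pairs$pos2)
  rec2 <- sprintf("%s\t%d\t%s\t%d\t60\t50M\t%s\t%d\t0\t*\t*",
                  pairs$pair_id, flag2, pairs$chrom2, pairs$pos2,
                  rnext2, pairs$pos1)
  recs <- character(2L * nrow(pairs))
  if (nrow(pairs)) {
    recs[seq(1L, length(recs), 2L)] <- rec1
    recs[seq(2L, length(recs), 2L)] <- rec2
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
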