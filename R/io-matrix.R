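#' Read an expression matrix and its design table
#'
#' The matrix TSV has sample ids in the header row and gene ids in the
#' first column; the design TSV has columns `sample_id` and `condition`.
#'
#' @param path Matrix TSV path.
#' @param design_path Design TSV path.
#' @return An [expr_matrix].
#' @export
read_matrix_tsv <- function(path, design_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a gene column plus samples")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]])) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value at gene ", ids[bad],
           ", sample ", colnames(vals)[j])
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expr_matrix(m, read_design_tsv(design_path))
}

#' Read a sample-to-condition design table
#'
#' @param path TSV with columns `sample_id` and `condition`.
#' @return Named character vector mapping sample id to condition.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% colnames(d)))
    stop("design file needs columns sample_id and condition")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample ids in design: ",
         d$sample_id[duplicated(d$sample_id)][1])
  stats::setNames(as.character(d$condition), d$sample_id)
}

#' Write an expression matrix (and optionally its design) to TSV
#'
#' @param em An [expr_matrix] or bare numeric matrix.
#' @param path Matrix TSV path.
#' @param design_path Optional design TSV path.
#' @param id_col Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(em, path, design_path = NULL, id_col = "gene_id") {
  m <- if (inherits(em, "expr_matrix")) em$values else em
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    if (!inherits(em, "expr_matrix"))
      stop("design output requires an expr_matrix")
    utils::write.table(
      data.frame(sample_id = names(em$condition),
                 condition = unname(em$condition)),
      design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
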