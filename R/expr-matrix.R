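#' Labeled expression matrix
#'
#' Light container bundling a genes x samples numeric matrix with the
#' sample-to-condition assignment. All pipeline stages that need to know
#' which samples form a treatment group consume and return this class.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must
#'   carry unique rownames (gene ids) and colnames (sample ids).
#' @param condition Named character vector mapping every sample id to a
#'   condition name, e.g. `c(S1 = "non-treat", ...)`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `condition`.
#' @export
expr_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must have gene rownames and sample colnames")
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in matrix rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in matrix columns")
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  condition <- condition[colnames(values)]
  structure(list(values = values, condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Per-condition means of an expression matrix
#'
#' @param em An [expr_matrix].
#' @return Numeric matrix, genes x conditions, columns in the order the
#'   conditions first appear in the design.
#' @export
condition_means <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  conds <- unique(unname(em$condition))
  out <- vapply(conds, function(cc) {
    cols <- names(em$condition)[em$condition == cc]
    rowMeans(em$values[, cols, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (nrow(em$values) == 1L) out <- matrix(out, nrow = 1L,
                                           dimnames = list(rownames(em$values), conds))
  out
}

#' Replace the value matrix, keeping the design
#' @noRd
with_values <- function(em, values) expr_matrix(values, em$condition)
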