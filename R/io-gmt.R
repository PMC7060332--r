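#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: set id, description, then member gene
#' ids. Duplicate members within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets; each element is a character vector of
#'   unique member ids with attribute `description`. Empty file gives an
#'   empty list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1], " has fewer than 3 fields")
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set ", f[1], " de-duplicated")
      members <- unique(members)
    }
    structure(members, description = f[2])
  })
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors, as from [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
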