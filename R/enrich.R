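#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation. The over-representation fold is
#' `(k/n) / (K/N)`.
#'
#' @param k Overlap between query and set.
#' @param n Query size.
#' @param K Set size within the universe.
#' @param N Universe size.
#' @return List with `p_value` and `over_representation` (0 when `k = 0`).
#' @examples
#' hypergeom_test(5, 5, 5, 10)  # p = 1/252
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (n > N || K > N || k < 0 || k > min(n, K))
    stop("invalid hypergeometric arguments: k=", k, " n=", n,
         " K=", K, " N=", N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (k == 0L || n == 0L || K == 0L) 0 else (k / n) / (K / N)
  list(p_value = p, over_representation = fold)
}

#' Gene-set over-representation of a query gene list
#'
#' Tests each set against the query with [hypergeom_test()], using the
#' intersection of the set with the universe as `K`. Query genes outside
#' the universe are dropped with a warning; sets with no universe member
#' are skipped. Results are ordered by descending over-representation,
#' then ascending p-value.
#'
#' @param query Character vector of gene ids (de-duplicated internally).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @return data.frame: `set_id`, `name`, `k`, `n`, `K`, `N`, `p_value`,
#'   `over_representation`, `genes` (comma-joined overlap).
#' @export
enrich_gene_list <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(unique(as.character(sets[[sid]])), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    overlap <- intersect(query, members)
    ht <- hypergeom_test(length(overlap), n, K, N)
    desc <- attr(sets[[sid]], "description")
    data.frame(set_id = sid,
               name = if (is.null(desc)) sid else desc,
               k = length(overlap), n = n, K = K, N = N,
               p_value = ht$p_value,
               over_representation = ht$over_representation,
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_id = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      over_representation = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(-out$over_representation, out$p_value), ]
  rownames(out) <- NULL
  out
}

#' Screen gene lists for significantly over-represented pathways
#'
#' Runs [enrich_gene_list()] for each named gene list and marks pathways
#' with raw `p < alpha` (strict) as significant. No multiple-testing
#' correction, matching a raw-p presentation.
#'
#' @param genelists Named list of character vectors (e.g. from
#'   [fold_change_gene_lists()]).
#' @param pathways Named list of gene sets.
#' @param universe Background gene ids.
#' @param alpha Significance threshold; default 0.05.
#' @return Named list (one per gene list) with `table` (full enrichment
#'   table plus `significant` column) and `significant` (character vector
#'   of significant set ids).
#' @export
pathway_screen <- function(genelists, pathways, universe, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  lapply(genelists, function(gl) {
    tab <- suppressWarnings(enrich_gene_list(gl, pathways, universe))
    tab$significant <- tab$p_value < alpha
    list(table = tab, significant = tab$set_id[tab$significant])
  })
}

#' Pathways common to all three comparisons of a restoration pattern
#'
#' `restored_up`: pathways significant among genes down after injury
#' (NMDA-saline vs non-treat) *and* up under both treatments (KUS121 and
#' KUS187 vs NMDA-saline). `restored_down` is the mirrored pattern
#' (injury-up, treatment-down).
#'
#' @param screens Output of [pathway_screen()] on the six fold-change
#'   lists; names must follow `up_A_vs_B` / `down_A_vs_B` with the design
#'   conditions.
#' @param conditions The four condition names, in design order.
#' @return List with elements `restored_up` and `restored_down`, each a
#'   data.frame of the common pathways carrying the three p-values and
#'   matched-entity counts.
#' @export
intersect_common_pathways <- function(screens,
                                      conditions = c("non-treat", "NMDA-saline",
                                                     "KUS121", "KUS187")) {
  inj <- paste0(conditions[2L], "_vs_", conditions[1L])
  k121 <- paste0(conditions[3L], "_vs_", conditions[2L])
  k187 <- paste0(conditions[4L], "_vs_", conditions[2L])
  pick <- function(name) {
    if (is.null(screens[[name]])) stop("missing screen: ", name)
    screens[[name]]
  }
  one_direction <- function(inj_list, trt_dir) {
    s_inj <- pick(paste0(inj_list, "_", inj))
    s_121 <- pick(paste0(trt_dir, "_", k121))
    s_187 <- pick(paste0(trt_dir, "_", k187))
    common <- Reduce(intersect, list(s_inj$significant, s_121$significant,
                                     s_187$significant))
    if (!length(common))
      return(data.frame(set_id = character(), name = character(),
                        stringsAsFactors = FALSE))
    grab <- function(scr, suffix) {
      tab <- scr$table[match(common, scr$table$set_id), ]
      stats::setNames(tab[, c("k", "p_value")],
                      paste0(c("matched_", "p_"), suffix))
    }
    nm <- s_inj$table$name[match(common, s_inj$table$set_id)]
    cbind(data.frame(set_id = common, name = nm, stringsAsFactors = FALSE),
          grab(s_121, "K121"), grab(s_187, "K187"), grab(s_inj, "injury"))
  }
  list(restored_up = one_direction("down", "up"),
       restored_down = one_direction("up", "down"))
}
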