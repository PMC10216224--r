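# Local over-representation analysis (hypergeometric upper tail) against
# GMT collections, with BH-FDR and a -log10(FDR) enrichment score.

#' Over-representation analysis
#'
#' For each gene set, tests the overlap between `gene_list` and the set
#' within `universe` with the hypergeometric upper tail
#' `p = P[X >= k]`, X ~ Hypergeometric(N, m, n), where N is the universe
#' size, m the set size in the universe, n the list size, and k the overlap.
#' BH-FDR is applied across all sets of the collection; the enrichment
#' score is `-log10(fdr)`. Rows are ordered by fdr then set name.
#'
#' @param gene_list Character vector of query genes.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Background gene vector; the list and all sets are
#'   intersected with it.
#' @param alpha FDR threshold for the `reportable` flag (default 0.05).
#' @return data.frame: set, k (overlap), m (set size), n (list size),
#'   N (universe size), p, fdr, score, reportable.
#' @export
ora <- function(gene_list, sets, universe, alpha = 0.05) {
  stopifnot(length(sets) > 0L)
  universe <- unique(toupper(universe))
  big_n <- length(universe)
  gene_list <- intersect(unique(toupper(gene_list)), universe)
  if (length(gene_list) == 0L) {
    warning("empty gene list after universe intersection")
    return(data.frame(set = character(), k = integer(), m = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), score = numeric(),
                      reportable = logical()))
  }
  n <- length(gene_list)
  out <- data.frame(
    set = names(sets),
    k = vapply(sets, function(s) length(intersect(toupper(s), gene_list)), 1L),
    m = vapply(sets, function(s) length(intersect(toupper(s), universe)), 1L),
    n = n, N = big_n,
    stringsAsFactors = FALSE, row.names = NULL)
  out$p <- stats::phyper(out$k - 1L, out$m, out$N - out$m, out$n,
                         lower.tail = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$score <- -log10(out$fdr)
  out$reportable <- out$fdr < alpha
  out <- out[order(out$fdr, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
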