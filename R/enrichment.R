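#' @include cotransfer.R
#' @importFrom stats phyper p.adjust
NULL

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric tail test per term: the p-value is
#' P(X >= observed overlap) for X hypergeometric with the term's genes as
#' successes in the background and the gene set's size drawn. A term with
#' zero overlap has p = 1 (P(X >= 0) = 1). Terms with `p < alpha` are
#' flagged enriched; Benjamini-Hochberg adjusted p-values are reported
#' alongside the raw ones.
#'
#' @param geneSet character vector of genes, a subset of `background`.
#' @param termMap data.frame with `term_id`, `term_name`, `gene_id` (one row
#'   per term-gene link; genes must lie in the background).
#' @param background character vector, the gene universe.
#' @param alpha enrichment threshold on the raw p-value, default 0.05.
#' @return data.frame per term: `term_id`, `term_name`, `set_count`,
#'   `background_count`, `p_value`, `p_adjust`, `enriched`.
#' @export
enrichTerms <- function(geneSet, termMap, background, alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% background))
    stop("gene set must be a subset of the background")
  termMap <- termMap[termMap$gene_id %in% background, , drop = FALSE]
  terms <- unique(termMap[, c("term_id", "term_name")])
  N <- length(background)
  n <- length(geneSet)
  res <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- unique(termMap$gene_id[termMap$term_id == terms$term_id[i]])
    K <- length(genes)
    k <- length(intersect(genes, geneSet))
    # P(X >= k); phyper's upper tail is strict, hence k - 1
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               set_count = k, background_count = K, p_value = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term_id = character(), term_name = character(),
                      set_count = integer(), background_count = integer(),
                      p_value = numeric(), p_adjust = numeric(),
                      enriched = logical()))
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out$enriched <- out$p_value < alpha
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
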