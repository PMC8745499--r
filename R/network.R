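#' @include tfFamilies.R
NULL

#' Export a lncRNA-mRNA/TF regulatory network
#'
#' Writes a Cytoscape-ready SIF edge list (`lncrna targets gene`), a TSV edge
#' table carrying the mode and scores, and a node-attribute table with roles
#' (`lncRNA`, `mRNA`, or `TF` when the gene appears in the family map).
#' Self-edges are refused.
#'
#' @param targetPairs data.frame with `lncrna_id`, `gene_id`, `mode` and
#'   optionally `distance_bp`/`ndG`/`cotransfer`.
#' @param dir output directory.
#' @param familyMap optional data.frame (`gene_id`, `family`) marking TF
#'   nodes.
#' @param prefix file name prefix, default `"network"`.
#' @return invisibly, the paths written (`sif`, `edges`, `nodes`).
#' @export
exportNetwork <- function(targetPairs, dir, familyMap = NULL,
                          prefix = "network") {
  if (any(targetPairs$lncrna_id == targetPairs$gene_id))
    stop("self-edges are not allowed")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(sprintf("%s targets %s", targetPairs$lncrna_id,
                     targetPairs$gene_id), sif)
  edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(targetPairs, edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  isTf <- if (is.null(familyMap)) character() else familyMap$gene_id
  nodes <- unique(data.frame(
    node = c(targetPairs$lncrna_id, targetPairs$gene_id),
    role = c(rep("lncRNA", nrow(targetPairs)),
             ifelse(targetPairs$gene_id %in% isTf, "TF", "mRNA"))))
  conflict <- nodes$node[duplicated(nodes$node)]
  if (length(conflict))
    stop("inconsistent node role(s): ", paste(unique(conflict), collapse = ", "))
  if (!is.null(familyMap)) {
    nodes$family <- familyMap$family[match(nodes$node, familyMap$gene_id)]
    nodes$family[is.na(nodes$family)] <- ""
  }
  nodesPath <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(nodes, nodesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sif = sif, edges = edges, nodes = nodesPath))
}

#' Read a network edge table back
#'
#' Round-trip companion of [exportNetwork()].
#'
#' @param path the `_edges.tsv` file.
#' @return data.frame of pairs.
#' @export
readNetworkEdges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Extract the subnetwork annotated with one term
#'
#' Keeps the pairs whose target gene carries the given term in the term map.
#'
#' @param targetPairs data.frame of pairs.
#' @param termMap data.frame with `term_id`, `gene_id`.
#' @param termId the term to extract.
#' @return the filtered pair table.
#' @export
filterNetworkByTerm <- function(targetPairs, termMap, termId) {
  genes <- unique(termMap$gene_id[termMap$term_id == termId])
  targetPairs[targetPairs$gene_id %in% genes, , drop = FALSE]
}
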