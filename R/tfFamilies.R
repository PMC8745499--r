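#' @include enrichment.R
NULL

#' Transcription-factor family tallies over targeted genes
#'
#' Groups a target-gene set by TF family using a user-supplied gene-to-family
#' map (TF prediction itself is table-driven) and counts, per family, the
#' number of targeted genes and the number of distinct lncRNAs targeting
#' them, sorted by lncRNA count then gene count (descending). Genes missing
#' from the map are tallied under `unassigned`.
#'
#' @param targetPairs data.frame with `lncrna_id`, `gene_id` (typically the
#'   mobile-lncRNA target pairs).
#' @param familyMap data.frame with `gene_id`, `family`.
#' @return data.frame per family: `family`, `n_genes`, `n_lncrnas`.
#' @export
assignTfFamilies <- function(targetPairs, familyMap) {
  if (!nrow(targetPairs))
    return(data.frame(family = character(), n_genes = integer(),
                      n_lncrnas = integer()))
  fam <- familyMap$family[match(targetPairs$gene_id, familyMap$gene_id)]
  fam[is.na(fam)] <- "unassigned"
  sp <- split(targetPairs, fam)
  out <- data.frame(
    family = names(sp),
    n_genes = vapply(sp, function(d) length(unique(d$gene_id)), integer(1)),
    n_lncrnas = vapply(sp, function(d) length(unique(d$lncrna_id)), integer(1)),
    row.names = NULL)
  out[order(-out$n_lncrnas, -out$n_genes, out$family), , drop = FALSE]
}

#' Generate a synthetic gene-to-family map
#'
#' Assigns a configurable fraction of genes to TF families with probabilities
#' proportional to supplied weights — a synthetic stand-in for an external
#' TF-prediction table, for testing and simulation only.
#'
#' @param geneIds character vector of gene ids.
#' @param families family names, default a plant-typical panel.
#' @param tfFraction fraction of genes assigned to any family.
#' @param weights sampling weights per family.
#' @return data.frame with `gene_id`, `family` (TF genes only).
#' @export
syntheticFamilyMap <- function(geneIds,
                               families = c("MYB", "bHLH", "NAC", "C2H2",
                                            "WRKY", "ERF", "bZIP", "GRAS"),
                               tfFraction = 0.2,
                               weights = rev(seq_along(families))) {
  n <- round(tfFraction * length(geneIds))
  tf <- sample(geneIds, n)
  data.frame(gene_id = tf,
             family = sample(families, n, replace = TRUE,
                             prob = weights / sum(weights)))
}
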