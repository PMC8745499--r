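#' @include transTargets.R
NULL

#' Flag co-transferred lncRNA-mRNA pairs
#'
#' Joins transcript-level mobility flags onto predicted target pairs: a pair
#' is co-transferred when both the lncRNA and its target gene are mobile
#' (moved in the same direction, being transcripts of the same species).
#'
#' @param targetPairs data.frame from [predictCisTargets()] /
#'   [predictTransTargets()] (needs `lncrna_id`, `gene_id`, `mode`).
#' @param mobileFlags named logical vector over transcripts; every id in the
#'   pairs must be present.
#' @return the pair table with `lncrna_mobile`, `gene_mobile`, `cotransfer`
#'   columns, plus a `counts` attribute of co-transfer tallies per mode.
#' @export
identifyCotransferPairs <- function(targetPairs, mobileFlags) {
  ids <- unique(c(targetPairs$lncrna_id, targetPairs$gene_id))
  missing <- setdiff(ids, names(mobileFlags))
  if (length(missing))
    stop("referential-integrity error: no mobility flag for ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  out <- targetPairs
  out$lncrna_mobile <- unname(mobileFlags[out$lncrna_id])
  out$gene_mobile <- unname(mobileFlags[out$gene_id])
  out$cotransfer <- out$lncrna_mobile & out$gene_mobile
  co <- out[out$cotransfer, , drop = FALSE]
  counts <- lapply(split(co, co$mode), function(d)
    c(pairs = nrow(d), lncrnas = length(unique(d$lncrna_id)),
      genes = length(unique(d$gene_id))))
  attr(out, "counts") <- counts
  out
}
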