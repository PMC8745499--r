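#' @include quantify.R
NULL

.txSpans <- function(genomes, ids) {
  ex <- transcriptExons(genomes)[ids]
  spans <- unlist(range(ex, ignore.strand = TRUE), use.names = FALSE)
  names(spans) <- ids
  spans
}

#' Predict cis targets of lncRNAs
#'
#' A protein-coding gene is a cis target of a lncRNA when the gap between
#' their genomic spans (full transcript extent, both strands eligible) is
#' strictly less than `window` bp; overlapping spans have distance 0. Both
#' transcripts must lie on the same genome.
#'
#' @param genomes a [GenomeSet].
#' @param lncIds lncRNA transcript ids.
#' @param geneIds protein-coding transcript ids on the same genome.
#' @param window window size in bp (default 100,000; strict `<`).
#' @return data.frame of pairs: `lncrna_id`, `gene_id`, `mode = "cis"`,
#'   `distance_bp`, `lncrna_strand`, `gene_strand`.
#' @export
predictCisTargets <- function(genomes, lncIds, geneIds, window = 100000L) {
  td <- txData(genomes)
  spL <- td$species[match(lncIds, td$transcript_id)]
  spG <- td$species[match(geneIds, td$transcript_id)]
  if (anyNA(spL) || anyNA(spG)) stop("unknown transcript id")
  if (length(unique(c(spL, spG))) > 1)
    stop("cis prediction requires all transcripts on the same genome")
  l <- .txSpans(genomes, lncIds)
  g <- .txSpans(genomes, geneIds)
  hits <- findOverlaps(l, g, maxgap = window - 1L, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), distance_bp = integer(),
                      lncrna_strand = character(), gene_strand = character()))
  qi <- queryHits(hits); si <- subjectHits(hits)
  d <- GenomicRanges::distance(l[qi], g[si], ignore.strand = TRUE)
  keep <- !is.na(d) & d < window
  data.frame(lncrna_id = lncIds[qi[keep]], gene_id = geneIds[si[keep]],
             mode = "cis", distance_bp = as.integer(d[keep]),
             lncrna_strand = td$strand[match(lncIds[qi[keep]], td$transcript_id)],
             gene_strand = td$strand[match(geneIds[si[keep]], td$transcript_id)],
             row.names = NULL)
}
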