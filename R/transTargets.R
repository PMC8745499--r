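#' @include cisTargets.R
NULL

#' Hybridization score between a lncRNA and an mRNA
#'
#' Best local antiparallel duplex found by dynamic programming between the
#' lncRNA (5'->3') and the mRNA (3'->5'), with per-pair contributions
#' G:C = -3, A:U = -2, G:U = -1 (arbitrary units) and a +4 penalty per
#' mismatch or gap. `dG` is the negated best local score and `ndG` its
#' normalization by the shorter sequence length; more negative means a
#' stronger predicted interaction.
#'
#' @param lncSeq,mrnaSeq non-empty sequences over A/C/G/U/T.
#' @param gapPenalty mismatch/gap cost (positive), default 4.
#' @return list with `dG` and `ndG`.
#' @export
transPairingScore <- function(lncSeq, mrnaSeq, gapPenalty = 4) {
  best <- cpp_hybridize(as.character(lncSeq), as.character(mrnaSeq), gapPenalty)
  dG <- -best
  list(dG = dG, ndG = dG / min(nchar(lncSeq), nchar(mrnaSeq)))
}

#' Predict trans targets by sequence complementarity
#'
#' Scores every lncRNA-mRNA pair with [transPairingScore()] and keeps pairs
#' whose normalized hybridization energy `ndG` is at or below the cutoff,
#' sorted by `ndG` ascending (strongest first). As in the source analysis
#' the intended use is mobile lncRNAs against the foreign species' mRNA
#' catalog, but any two sequence sets can be supplied.
#'
#' @param lncSeqs named character vector (or `DNAStringSet`) of lncRNA
#'   sequences.
#' @param mrnaSeqs named character vector of mRNA sequences.
#' @param ndgCutoff keep pairs with `ndG <= ndgCutoff` (default -0.1).
#' @param gapPenalty mismatch/gap cost, default 4.
#' @return data.frame of pairs: `lncrna_id`, `gene_id`, `mode = "trans"`,
#'   `ndG`.
#' @export
predictTransTargets <- function(lncSeqs, mrnaSeqs, ndgCutoff = -0.1,
                                gapPenalty = 4) {
  lncSeqs <- vapply(lncSeqs, as.character, "")
  mrnaSeqs <- vapply(mrnaSeqs, as.character, "")
  if (is.null(names(lncSeqs)) || is.null(names(mrnaSeqs)))
    stop("sequence vectors must be named by transcript id")
  if (!is.finite(ndgCutoff) || !length(lncSeqs) || !length(mrnaSeqs)) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), ndG = numeric()))
  }
  sc <- cpp_hybridize_cross(unname(lncSeqs), unname(mrnaSeqs), gapPenalty)
  minLen <- outer(nchar(lncSeqs), nchar(mrnaSeqs), pmin)
  ndg <- -sc / minLen
  keep <- which(ndg <= ndgCutoff, arr.ind = TRUE)
  out <- data.frame(lncrna_id = names(lncSeqs)[keep[, 1]],
                    gene_id = names(mrnaSeqs)[keep[, 2]],
                    mode = "trans",
                    ndG = ndg[keep], row.names = NULL)
  out[order(out$ndG, out$lncrna_id, out$gene_id), , drop = FALSE]
}
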