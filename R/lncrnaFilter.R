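#' @include classCode.R codingPotential.R
NULL

#' Structural and expression filters of the lncRNA cascade
#'
#' Applies the first three identification filters to candidate transcripts:
#' (1) class code in i/x/u/o/e, (2) spliced length >= 200 nt and exon count
#' >= 2, (3) FPKM >= 0.1 in at least one tissue (a transcript expressed
#' anywhere stays a candidate). Transcripts absent from the expression matrix
#' are treated as FPKM 0 and logged. Every rejection records which filter(s)
#' failed.
#'
#' @param classCodes named character vector of class codes (candidate ids).
#' @param genomes [GenomeSet] providing lengths and exon counts.
#' @param se expression matrix from [computeFpkm()] (or any matrix-bearing
#'   object whose `fpkm` assay has candidate rows), optional: omit to skip
#'   the expression filter.
#' @param minLength,minExons,minFpkm filter thresholds (defaults 200, 2, 0.1;
#'   boundaries inclusive).
#' @return [S4Vectors::DataFrame] with per-filter pass flags and `passed`.
#' @export
filterCandidates <- function(classCodes, genomes, se = NULL,
                             minLength = 200L, minExons = 2L, minFpkm = 0.1) {
  ids <- names(classCodes)
  td <- txData(genomes)
  m <- match(ids, td$transcript_id)
  if (anyNA(m)) stop("unknown candidate transcript(s): ",
                     paste(ids[is.na(m)], collapse = ", "))
  len <- td$spliced_length[m]
  nex <- lengths(transcriptExons(genomes)[ids])
  pass_class <- classCodes %in% c("i", "x", "u", "o", "e")
  pass_length <- len >= minLength
  pass_exons <- nex >= minExons
  if (!is.null(se)) {
    fpkm <- assay(se, "fpkm")
    maxf <- rep(0, length(ids))
    hit <- ids %in% rownames(fpkm)
    if (any(!hit))
      message(sum(!hit), " candidates absent from the expression matrix; ",
              "treated as FPKM 0")
    maxf[hit] <- apply(fpkm[ids[hit], , drop = FALSE], 1, max)
    pass_fpkm <- maxf >= minFpkm
  } else {
    maxf <- rep(NA_real_, length(ids))
    pass_fpkm <- rep(TRUE, length(ids))
  }
  DataFrame(transcript_id = ids, class_code = unname(classCodes),
            spliced_length = len, exon_count = as.integer(nex),
            max_fpkm = maxf,
            pass_class = pass_class, pass_length = pass_length,
            pass_exons = pass_exons, pass_fpkm = pass_fpkm,
            passed = pass_class & pass_length & pass_exons & pass_fpkm)
}

#' The full five-step lncRNA identification cascade
#'
#' Chains the structural/expression filters with the coding-potential test
#' (filters 4-5: ORF rule plus optional protein-motif list) and classifies
#' the survivors by position. The cascade is monotone (each step only
#' removes transcripts) and idempotent.
#'
#' @param candidates character vector of candidate transcript ids.
#' @param genomes [GenomeSet] containing candidates and the reference
#'   annotation.
#' @param se expression matrix, optional (see [filterCandidates()]).
#' @param reference ids of reference (annotation) transcripts; default: all
#'   mRNA-biotype transcripts of the same species as each candidate.
#' @param motifs optional protein motif regular expressions.
#' @param ... thresholds passed to [filterCandidates()] and
#'   [codingPotential()].
#' @return [S4Vectors::DataFrame] with filter flags, coding-potential
#'   columns, `passed_filters` and `lncrna_type` (`NA` unless passed).
#' @export
identifyLncrnas <- function(candidates, genomes, se = NULL, reference = NULL,
                            motifs = NULL, ...) {
  td <- txData(genomes)
  if (is.null(reference))
    reference <- td$transcript_id[td$biotype == "mRNA"]
  codes <- character(length(candidates))
  names(codes) <- candidates
  for (sp in unique(td$species[match(candidates, td$transcript_id)])) {
    cIds <- candidates[td$species[match(candidates, td$transcript_id)] == sp]
    rIds <- reference[td$species[match(reference, td$transcript_id)] == sp]
    codes[cIds] <- assignClassCode(transcriptExons(genomes)[cIds],
                                   transcriptExons(genomes)[rIds])
  }
  flags <- filterCandidates(codes, genomes, se)
  cp <- codingPotential(splicedSeqs(genomes)[candidates], motifs = motifs, ...)
  out <- cbind(flags, cp)
  out$passed_filters <- out$passed & !out$is_coding
  out$lncrna_type <- NA_character_
  if (any(out$passed_filters))
    out$lncrna_type[out$passed_filters] <-
      classifyLncrnaType(out$class_code[out$passed_filters])
  out
}
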