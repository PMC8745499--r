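#' @include assignment.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom GenomicRanges GRanges findOverlaps start end width strand seqnames
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Exon lookup tables used to project transcript-space alignments to the
# genome and to attribute genomic alignments to transcripts.
.exonTable <- function(genomes) {
  ex <- transcriptExons(genomes)
  n <- lengths(ex)
  gr <- unlist(ex, use.names = FALSE)
  w <- width(gr)
  txid <- rep(names(ex), n)
  # cumulative spliced coordinates in transcript (5'->3') order
  cumEnd <- unlist(unname(tapply(w, factor(txid, levels = unique(txid)),
                                 cumsum, simplify = FALSE)), use.names = FALSE)
  cumStart <- cumEnd - w + 1L
  data.frame(transcript_id = txid,
             chrom = as.character(seqnames(gr)),
             g_start = start(gr), g_end = end(gr),
             strand = as.character(strand(gr)),
             cum_start = cumStart, cum_end = cumEnd,
             stringsAsFactors = FALSE)
}

# Genomic alignment blocks for located fragments. `lab` must have hit_ref,
# hit_pos, hit_strand, hit_is_transcript, hit_len and origin_species.
# Returns a data.frame of blocks keyed by fragment row index.
.fragmentBlocks <- function(lab, exTab, txMeta) {
  n <- nrow(lab)
  idx <- seq_len(n)
  isTx <- lab$hit_is_transcript %in% TRUE
  blocks <- vector("list", 2L)
  if (any(!isTx & !is.na(lab$hit_ref))) {
    g <- which(!isTx & !is.na(lab$hit_ref))
    blocks[[1]] <- data.frame(
      fragment = g, chrom = lab$hit_ref[g],
      start = lab$hit_pos[g],
      end = lab$hit_pos[g] + lab$hit_len[g] - 1L,
      strand = lab$hit_strand[g], stringsAsFactors = FALSE)
  }
  if (any(isTx)) {
    t <- which(isTx)
    txid <- lab$hit_ref[t]
    s <- lab$hit_pos[t]
    e <- s + lab$hit_len[t] - 1L
    rows <- split(seq_len(nrow(exTab)), exTab$transcript_id)
    hit <- rows[txid]
    nper <- lengths(hit)
    eIdx <- unlist(hit, use.names = FALSE)
    fIdx <- rep(t, nper)
    sF <- rep(s, nper); eF <- rep(e, nper)
    et <- exTab[eIdx, ]
    keep <- et$cum_start <= eF & et$cum_end >= sF
    et <- et[keep, ]; fIdx <- fIdx[keep]; sF <- sF[keep]; eF <- eF[keep]
    os <- pmax(sF, et$cum_start) - et$cum_start
    oe <- pmin(eF, et$cum_end) - et$cum_start
    plus <- et$strand == "+"
    bs <- ifelse(plus, et$g_start + os, et$g_end - oe)
    be <- ifelse(plus, et$g_start + oe, et$g_end - os)
    # fragment sense strand on the genome: alignment to the transcript in
    # '+' orientation means the fragment follows the transcript's strand
    txStrand <- et$strand
    fragStrand <- ifelse(lab$hit_strand[fIdx] == "+", txStrand,
                         ifelse(txStrand == "+", "-", "+"))
    blocks[[2]] <- data.frame(fragment = fIdx, chrom = et$chrom,
                              start = as.integer(bs), end = as.integer(be),
                              strand = fragStrand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(fragment = integer(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  out[order(out$fragment, out$start), , drop = FALSE]
}

# For each fragment, transcripts whose exons its blocks overlap on the
# matching strand; multi-overlap fragments are split 1/n.
.locateFragments <- function(lab, genomes) {
  td <- txData(genomes)
  exTab <- .exonTable(genomes)
  lab$hit_len <- as.integer(lab$hit_len)
  bl <- .fragmentBlocks(lab, exTab, td)
  exGr <- GRanges(exTab$chrom, IRanges(exTab$g_start, exTab$g_end),
                  strand = exTab$strand)
  blGr <- GRanges(bl$chrom, IRanges(bl$start, bl$end), strand = bl$strand)
  ov <- findOverlaps(blGr, exGr, ignore.strand = TRUE)
  sameStrand <- bl$strand[queryHits(ov)] == exTab$strand[subjectHits(ov)]
  ov <- ov[sameStrand]
  pairs <- unique(data.frame(fragment = bl$fragment[queryHits(ov)],
                             transcript_id = exTab$transcript_id[subjectHits(ov)],
                             stringsAsFactors = FALSE))
  nPer <- table(pairs$fragment)
  pairs$weight <- 1 / as.numeric(nPer[as.character(pairs$fragment)])
  located <- which(!is.na(lab$hit_ref))
  list(pairs = pairs,
       intergenic = setdiff(located, unique(pairs$fragment)),
       blocks = bl)
}

#' Count fragments per transcript and tissue
#'
#' Attributes every genome-matched fragment of each tissue library to the
#' transcript(s) whose exons its (splice-aware, strand-matched) alignment
#' blocks overlap; fragments overlapping n transcripts count 1/n to each, and
#' fragments in unannotated regions go to a logged intergenic bucket.
#' Mobile-labeled fragments of a stem tissue count toward the foreign
#' species' transcripts in that tissue's column. Mobile-derived counts are
#' tallied separately for the transcript-level mobility call.
#'
#' @param summaries named list with elements `parasite_stem`, `interface`,
#'   `host_stem`: [AssignmentSummary] objects for the stems and the list
#'   returned by [assignInterfaceLibrary()] for the interface (any subset of
#'   tissues is accepted).
#' @param genomes the [GenomeSet].
#' @param readLength read length used for alignment blocks.
#' @return list with `counts` (transcript x tissue matrix, fractional),
#'   `mobile_counts` (same shape, mobile-labeled fragments only),
#'   `intergenic` and `totals` (named per tissue; totals are all
#'   genome-matched fragments).
#' @export
countFragments <- function(summaries, genomes, readLength) {
  td <- txData(genomes)
  tissues <- names(summaries)
  counts <- matrix(0, nrow(td), length(tissues),
                   dimnames = list(td$transcript_id, tissues))
  mobile <- matrix(0, nrow(td), length(tissues),
                   dimnames = list(td$transcript_id, tissues))
  intergenic <- stats::setNames(numeric(length(tissues)), tissues)
  totals <- stats::setNames(numeric(length(tissues)), tissues)
  for (tissue in tissues) {
    s <- summaries[[tissue]]
    lab <- if (is(s, "AssignmentSummary")) readLabels(s) else s$labels
    keep <- !is.na(lab$origin_species)
    lab <- lab[keep, , drop = FALSE]
    totals[tissue] <- nrow(lab)
    if (!nrow(lab)) next
    lab$hit_len <- readLength
    loc <- .locateFragments(lab, genomes)
    if (nrow(loc$pairs)) {
      agg <- stats::aggregate(weight ~ transcript_id, loc$pairs, sum)
      counts[agg$transcript_id, tissue] <- agg$weight
      isMob <- lab$label[loc$pairs$fragment] == "mobile"
      if (any(isMob)) {
        aggM <- stats::aggregate(weight ~ transcript_id,
                                 loc$pairs[isMob, , drop = FALSE], sum)
        mobile[aggM$transcript_id, tissue] <- aggM$weight
      }
    }
    intergenic[tissue] <- length(loc$intergenic)
    if (intergenic[tissue] > 0)
      message(intergenic[tissue], " fragments in unannotated regions (",
              tissue, ") counted as intergenic")
  }
  list(counts = counts, mobile_counts = mobile, intergenic = intergenic,
       totals = totals)
}

#' Compute FPKM and assemble the expression matrix
#'
#' FPKM = fragments x 10^9 / (total mapped fragments x spliced length in bp).
#' Totals are per tissue and include intergenic fragments (every
#' genome-matched fragment is "mapped").
#'
#' @param countRes result of [countFragments()].
#' @param genomes the [GenomeSet].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   `counts`, `mobile_counts` and `fpkm`; rowData carries the transcript
#'   catalog and `metadata()$totals` the per-tissue totals.
#' @export
computeFpkm <- function(countRes, genomes) {
  td <- txData(genomes)
  counts <- countRes$counts
  totals <- countRes$totals
  if (any(totals == 0))
    stop("undefined expression matrix: tissue(s) with zero mapped fragments: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  len <- td$spliced_length[match(rownames(counts), td$transcript_id)]
  fpkm <- counts * 1e9 / (rep(totals, each = nrow(counts)) * len)
  se <- SummarizedExperiment(
    assays = list(counts = counts, mobile_counts = countRes$mobile_counts,
                  fpkm = fpkm),
    rowData = td[match(rownames(counts), td$transcript_id), ],
    colData = DataFrame(tissue = colnames(counts),
                        total_mapped_fragments = totals,
                        row.names = colnames(counts)))
  S4Vectors::metadata(se)$totals <- totals
  S4Vectors::metadata(se)$intergenic <- countRes$intergenic
  se
}
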