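#' @include lncrnaFilter.R
NULL

#' Transcript feature table
#'
#' Spliced length, exon count and longest forward-frame ORF length for a set
#' of transcripts — the inputs of [featureSummary()].
#'
#' @param genomes a [GenomeSet].
#' @param ids transcript ids.
#' @return data.frame with `transcript_id`, `spliced_length`, `exon_count`,
#'   `orf_length`.
#' @export
txFeatures <- function(genomes, ids) {
  td <- txData(genomes)
  m <- match(ids, td$transcript_id)
  orf <- vapply(splicedSeqs(genomes)[ids],
                function(s) .forwardLongestOrf(s)$length, integer(1))
  data.frame(transcript_id = ids,
             spliced_length = td$spliced_length[m],
             exon_count = as.integer(lengths(transcriptExons(genomes)[ids])),
             orf_length = unname(orf))
}

.binCounts <- function(x, from, by) {
  top <- max(x, from)
  breaks <- seq(from, by * ceiling((top + 1) / by), by = by)
  if (min(x) < from) breaks <- c(min(x), breaks)
  h <- table(cut(x, breaks = breaks, right = FALSE,
                 labels = sprintf("[%d,%d)", head(breaks, -1), breaks[-1])))
  data.frame(bin = names(h), count = as.integer(h), row.names = NULL)
}

#' Comparative feature distributions of lncRNAs and mRNAs
#'
#' Distribution tables in the conventional binning: spliced fraction (exon
#' count >= 2), exon-count histogram over 1..16 with a `>16` bucket,
#' transcript-length histogram in 200-bp bins from 200 bp, and ORF-length
#' histogram in 100-nt bins; means of lengths and ORF lengths are reported.
#'
#' @param lncFeatures,mrnaFeatures non-empty data.frames from
#'   [txFeatures()].
#' @return nested list with per-set `spliced_fraction`, `exon_hist`,
#'   `length_hist`, `orf_hist`, `mean_length`, `mean_orf`.
#' @export
featureSummary <- function(lncFeatures, mrnaFeatures) {
  if (!nrow(lncFeatures) || !nrow(mrnaFeatures))
    stop("both transcript sets must be non-empty")
  one <- function(f) {
    ex <- pmin(f$exon_count, 17L)
    exh <- table(factor(ex, levels = 1:17,
                        labels = c(as.character(1:16), ">16")))
    list(n = nrow(f),
         spliced_fraction = mean(f$exon_count >= 2),
         exon_hist = data.frame(exons = names(exh), count = as.integer(exh)),
         length_hist = .binCounts(f$spliced_length, 200L, 200L),
         orf_hist = .binCounts(f$orf_length, 0L, 100L),
         mean_length = mean(f$spliced_length),
         mean_orf = mean(f$orf_length))
  }
  list(lncRNA = one(lncFeatures), mRNA = one(mrnaFeatures))
}
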