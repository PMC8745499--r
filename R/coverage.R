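#' @include quantify.R
NULL

#' Per-base coverage and junction evidence for one transcript
#'
#' Computes the read-depth track over a transcript's genomic span from one
#' tissue's located fragments, plus the junction count per intron (fragments
#' whose alignment blocks skip exactly that intron). For a foreign tissue
#' (the transcript's species is not the tissue's native species) only
#' mobile-labeled fragments contribute, matching the evidence display for
#' mobile transcripts: mature (spliced) molecules show zero intronic depth.
#'
#' @param summary an [AssignmentSummary] (stem) or the list from
#'   [assignInterfaceLibrary()].
#' @param transcript transcript id.
#' @param genomes the [GenomeSet].
#' @param readLength read length in bp.
#' @param mobileOnly use only mobile-labeled fragments (default: automatic —
#'   `TRUE` when the transcript's species differs from the stem tissue's
#'   native species).
#' @return list with `transcript`, `tissue`, `span` (chrom/start/end),
#'   `depth` (integer vector over the span), `introns` (data.frame with
#'   start, end, junction_count), `n_fragments`.
#' @export
coverageTrack <- function(summary, transcript, genomes, readLength,
                          mobileOnly = NULL) {
  td <- txData(genomes)
  row <- td[td$transcript_id == transcript, , drop = FALSE]
  if (!nrow(row)) stop("unknown transcript: ", transcript)
  isStem <- is(summary, "AssignmentSummary")
  lab <- if (isStem) readLabels(summary) else summary$labels
  tissue <- if (isStem) summary@tissue else "interface"
  if (is.null(mobileOnly))
    mobileOnly <- isStem && grepl("_stem$", tissue) &&
      sub("_stem$", "", tissue) != row$species
  if (mobileOnly) lab <- lab[lab$label %in% "mobile", , drop = FALSE]
  lab <- lab[!is.na(lab$origin_species) & lab$origin_species == row$species, ,
             drop = FALSE]
  ex <- transcriptExons(genomes)[[transcript]]
  spanStart <- min(start(ex)); spanEnd <- max(end(ex))
  depth <- integer(spanEnd - spanStart + 1L)
  exSorted <- sort(ex, ignore.strand = TRUE)
  introns <- if (length(exSorted) > 1)
    data.frame(start = head(end(exSorted), -1) + 1L,
               end = tail(start(exSorted), -1) - 1L,
               junction_count = 0L)
  else data.frame(start = integer(), end = integer(),
                  junction_count = integer())
  nFrag <- 0L
  if (nrow(lab)) {
    lab$hit_len <- readLength
    bl <- .fragmentBlocks(lab, .exonTable(genomes), td)
    bl <- bl[bl$chrom == row$chrom & bl$end >= spanStart & bl$start <= spanEnd, ,
             drop = FALSE]
    if (nrow(bl)) {
      nFrag <- length(unique(bl$fragment))
      s <- pmax(bl$start, spanStart) - spanStart + 1L
      e <- pmin(bl$end, spanEnd) - spanStart + 1L
      for (i in seq_along(s)) depth[s[i]:e[i]] <- depth[s[i]:e[i]] + 1L
      # junction evidence: consecutive blocks of a fragment skipping exactly
      # one annotated intron
      if (nrow(introns)) {
        spl <- split(bl, bl$fragment)
        for (b in spl) {
          if (nrow(b) < 2) next
          b <- b[order(b$start), ]
          gs <- head(b$end, -1) + 1L
          ge <- tail(b$start, -1) - 1L
          for (j in seq_along(gs)) {
            hit <- which(introns$start == gs[j] & introns$end == ge[j])
            if (length(hit))
              introns$junction_count[hit] <- introns$junction_count[hit] + 1L
          }
        }
      }
    }
  }
  list(transcript = transcript, tissue = tissue,
       span = list(chrom = row$chrom, start = spanStart, end = spanEnd),
       depth = depth, introns = introns, n_fragments = nFrag)
}

#' Write a coverage track as BedGraph
#'
#' Converts the 1-based closed per-base depth track to the 0-based half-open
#' BedGraph convention, merging runs of equal depth.
#'
#' @param track result of [coverageTrack()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeBedGraph <- function(track, path) {
  d <- track$depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0
  g0 <- track$span$start - 1L
  df <- data.frame(chrom = track$span$chrom,
                   start = g0 + starts[keep] - 1L,
                   end = g0 + ends[keep],
                   depth = r$values[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s %s\"",
                     track$transcript, track$tissue), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean intronic depth of a coverage track
#'
#' Average per-base depth over the transcript's annotated introns; 0 for a
#' track built from mature (fully spliced) molecules.
#'
#' @param track result of [coverageTrack()].
#' @return a single numeric value (`NA` when the transcript has no introns).
#' @export
intronicDepth <- function(track) {
  if (!nrow(track$introns)) return(NA_real_)
  off <- track$span$start - 1L
  vals <- unlist(lapply(seq_len(nrow(track$introns)), function(i) {
    track$depth[(track$introns$start[i] - off):(track$introns$end[i] - off)]
  }))
  mean(vals)
}
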