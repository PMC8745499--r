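#' @include seedIndex.R
NULL

# rule table shared by the internal matcher and the SAM ingest path
.labelFromMatches <- function(matchedNative, matchedForeign) {
  ifelse(matchedNative, "native",
         ifelse(matchedForeign, "mobile", "filtered"))
}

#' Classify single reads as native, mobile or filtered
#'
#' The dual-genome rule: a read matching the native genome (alone or together
#' with the foreign genome) is native; a read matching only the foreign
#' genome is mobile; a read matching neither is filtered out as a sequencing
#' artefact.
#'
#' @param reads character vector of read sequences.
#' @param nativeIndex [SeedIndex] of the tissue's own species.
#' @param foreignIndex [SeedIndex] of the other species.
#' @param params an [assignmentParams()] list.
#' @return character vector of labels in `native`/`mobile`/`filtered`.
#' @export
assignRead <- function(reads, nativeIndex, foreignIndex,
                       params = assignmentParams()) {
  mn <- matchGenome(reads, nativeIndex, params)
  mf <- matchGenome(reads, foreignIndex, params)
  .labelFromMatches(mn$matched, mf$matched)
}

# Per-fragment best-hit columns: prefer mate1's hit; fall back to mate2,
# whose alignment strand is antisense to the fragment and is flipped.
.pickHits <- function(m1, m2, use) {
  useM1 <- m1$matched & use
  useM2 <- !m1$matched & m2$matched & use
  n <- length(use)
  out <- list(ref = rep(NA_character_, n), pos = rep(NA_integer_, n),
              strand = rep(NA_character_, n), isTx = rep(NA, n),
              mate = rep(NA_integer_, n))
  out$ref[useM1] <- m1$ref[useM1];   out$ref[useM2] <- m2$ref[useM2]
  out$pos[useM1] <- m1$pos[useM1];   out$pos[useM2] <- m2$pos[useM2]
  out$strand[useM1] <- m1$strand[useM1]
  out$strand[useM2] <- ifelse(m2$strand[useM2] == "+", "-", "+")
  out$isTx[useM1] <- m1$ref_is_transcript[useM1]
  out$isTx[useM2] <- m2$ref_is_transcript[useM2]
  out$mate[useM1] <- 1L; out$mate[useM2] <- 2L
  out
}

.hitColumns <- function(pick, n, m1n, m2n, m1f, m2f, nativeSp, foreignSp) {
  hn <- .pickHits(m1n, m2n, pick == "native")
  hf <- .pickHits(m1f, m2f, pick == "mobile")
  sel <- !is.na(hf$mate)
  for (f in names(hn)) hn[[f]][sel] <- hf[[f]][sel]
  origin <- rep(NA_character_, n)
  origin[pick == "native"] <- nativeSp
  origin[pick == "mobile"] <- foreignSp
  DataFrame(origin_species = origin, hit_ref = hn$ref, hit_pos = hn$pos,
            hit_strand = hn$strand, hit_is_transcript = hn$isTx,
            hit_mate = hn$mate)
}

#' Assign every fragment of one stem library
#'
#' Labels each read pair of a pure stem tissue via the native/mobile/filtered
#' rule. A fragment counts as matched to a genome when at least one mate
#' matches it; pairs whose mates match opposite genomes exclusively (one
#' native-only, the other foreign-only) are conservatively filtered and
#' tallied as conflicts. The foreign-read proportion is
#' mobile / (mobile + native), `NA` for an empty library.
#'
#' @param reads per-tissue [S4Vectors::DataFrame] from [simulateLibraries()],
#'   or any DataFrame with `read_id`, `mate1`, `mate2` columns.
#' @param nativeIndex [SeedIndex] of the tissue's species.
#' @param foreignIndex [SeedIndex] of the other species.
#' @param params an [assignmentParams()] list.
#' @param tissue tissue label recorded in the summary.
#' @return an [AssignmentSummary].
#' @export
assignLibrary <- function(reads, nativeIndex, foreignIndex,
                          params = assignmentParams(),
                          tissue = if (nrow(reads)) reads$tissue[1] else "library") {
  n <- nrow(reads)
  if (n == 0) {
    return(new("AssignmentSummary", tissue = tissue,
               counts = c(native = 0, mobile = 0, filtered = 0),
               conflicts = 0, labels = DataFrame()))
  }
  m1n <- matchGenome(reads$mate1, nativeIndex, params)
  m2n <- matchGenome(reads$mate2, nativeIndex, params)
  m1f <- matchGenome(reads$mate1, foreignIndex, params)
  m2f <- matchGenome(reads$mate2, foreignIndex, params)
  matchedN <- m1n$matched | m2n$matched
  matchedF <- m1f$matched | m2f$matched
  m1NativeOnly <- m1n$matched & !m1f$matched
  m1ForeignOnly <- m1f$matched & !m1n$matched
  m2NativeOnly <- m2n$matched & !m2f$matched
  m2ForeignOnly <- m2f$matched & !m2n$matched
  conflict <- (m1NativeOnly & m2ForeignOnly) | (m1ForeignOnly & m2NativeOnly)
  label <- .labelFromMatches(matchedN, matchedF)
  label[conflict] <- "filtered"
  hits <- .hitColumns(label, n, m1n, m2n, m1f, m2f,
                      nativeIndex@species, foreignIndex@species)
  labels <- cbind(DataFrame(read_id = reads$read_id, label = label,
                            conflict = conflict), hits)
  new("AssignmentSummary", tissue = tissue,
      counts = c(native = sum(label == "native"),
                 mobile = sum(label == "mobile"),
                 filtered = sum(label == "filtered")),
      conflicts = sum(conflict), labels = labels)
}

#' Assign interface-library fragments per species of origin
#'
#' The interface tissue contains both species' RNA and has no single native
#' species, so its reads are labeled by origin (`parasite`, `host`, `both`
#' for the rare fragment matching both references, `filtered`) with no mobile
#' category; mobility is computed only from the pure stem tissues.
#'
#' @param reads interface [S4Vectors::DataFrame] (`read_id`, `mate1`, `mate2`).
#' @param parasiteIndex,hostIndex per-species [SeedIndex] objects.
#' @param params an [assignmentParams()] list.
#' @return list with `counts` and a per-fragment `labels` DataFrame.
#' @export
assignInterfaceLibrary <- function(reads, parasiteIndex, hostIndex,
                                   params = assignmentParams()) {
  n <- nrow(reads)
  m1p <- matchGenome(reads$mate1, parasiteIndex, params)
  m2p <- matchGenome(reads$mate2, parasiteIndex, params)
  m1h <- matchGenome(reads$mate1, hostIndex, params)
  m2h <- matchGenome(reads$mate2, hostIndex, params)
  mp <- m1p$matched | m2p$matched
  mh <- m1h$matched | m2h$matched
  label <- ifelse(mp & mh, "both",
                  ifelse(mp, "parasite", ifelse(mh, "host", "filtered")))
  hp <- .pickHits(m1p, m2p, label %in% c("parasite", "both"))
  hh <- .pickHits(m1h, m2h, label == "host")
  sel <- !is.na(hh$mate)
  for (f in names(hp)) hp[[f]][sel] <- hh[[f]][sel]
  origin <- rep(NA_character_, n)
  origin[label %in% c("parasite", "both")] <- "parasite"
  origin[label == "host"] <- "host"
  labels <- DataFrame(read_id = reads$read_id, label = label,
                      origin_species = origin, hit_ref = hp$ref,
                      hit_pos = hp$pos, hit_strand = hp$strand,
                      hit_is_transcript = hp$isTx, hit_mate = hp$mate)
  list(counts = c(parasite = sum(label == "parasite"),
                  host = sum(label == "host"),
                  both = sum(label == "both"),
                  filtered = sum(label == "filtered")),
       labels = labels)
}

#' Split the foreign-read proportion by transcript biotype
#'
#' Recomputes the mobile/(mobile+native) proportion separately for fragments
#' whose alignment falls in lncRNA versus mRNA transcripts of the catalog
#' (fragments outside any annotated transcript are reported as `intergenic`).
#'
#' @param summary an [AssignmentSummary] for a stem tissue.
#' @param genomes the [GenomeSet] with the transcript catalog.
#' @param readLength read length in bp, used for alignment extents.
#' @return data.frame with per-biotype native/mobile counts and proportions.
#' @export
proportionByBiotype <- function(summary, genomes, readLength) {
  lab <- readLabels(summary)
  lab <- lab[lab$label %in% c("native", "mobile"), , drop = FALSE]
  lab$hit_len <- as.integer(readLength)
  loc <- .locateFragments(lab, genomes)
  # primary transcript per fragment (fragments keep one biotype even when
  # their count is split across transcripts)
  primary <- loc$pairs[!duplicated(loc$pairs$fragment), , drop = FALSE]
  frag <- seq_len(nrow(lab))
  bt <- rep("intergenic", nrow(lab))
  m <- match(frag, primary$fragment)
  hit <- !is.na(m)
  bt[hit] <- txData(genomes)$biotype[match(primary$transcript_id[m[hit]],
                                           txData(genomes)$transcript_id)]
  bt[bt == "lncRNA-truth"] <- "lncRNA"
  tab <- table(biotype = bt, label = factor(lab$label,
                                            c("native", "mobile")))
  out <- as.data.frame.matrix(tab)
  out$biotype <- rownames(out)
  out$foreign_proportion <- ifelse(out$native + out$mobile > 0,
                                   out$mobile / (out$native + out$mobile),
                                   NA_real_)
  rownames(out) <- NULL
  out[, c("biotype", "native", "mobile", "foreign_proportion")]
}
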