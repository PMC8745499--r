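#' @include assignment.R
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
NULL

.samMatched <- function(path, mapqFloor) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 11))
    stop("malformed SAM in ", path, " at line ", body[which(nf < 11)[1]],
         ": fewer than 11 fields")
  isBam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (isBam) path else
    suppressMessages(Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                      indexDestination = FALSE))
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq")))[[1]]
  primary <- bitwAnd(rec$flag, 0x100L) == 0L & bitwAnd(rec$flag, 0x800L) == 0L
  mapped <- bitwAnd(rec$flag, 0x4L) == 0L
  q <- rec$mapq
  q[is.na(q)] <- 0L
  ok <- primary & mapped & q >= mapqFloor
  list(all = unique(rec$qname), matched = unique(rec$qname[ok]))
}

#' Ingest external alignments and label reads
#'
#' Real-data path replacing the internal matcher: a read is "matched" to a
#' genome when it has at least one primary alignment with mapping quality at
#' or above `mapq_floor` in that genome's SAM/BAM file; labels then follow
#' the native/mobile/filtered rule table. Reads present in only one file are
#' treated as unmatched in the missing one and logged.
#'
#' @param nativeSam,foreignSam SAM (or BAM) files aligned against the native
#'   and foreign genome respectively; same read universe.
#' @param params an [assignmentParams()] list (`mapq_floor` is used).
#' @return [S4Vectors::DataFrame] with `read_id` and `label`.
#' @export
ingestAlignments <- function(nativeSam, foreignSam,
                             params = assignmentParams()) {
  nat <- .samMatched(nativeSam, params$mapq_floor)
  fon <- .samMatched(foreignSam, params$mapq_floor)
  universe <- sort(union(nat$all, fon$all))
  onlyOne <- length(setdiff(nat$all, fon$all)) + length(setdiff(fon$all, nat$all))
  if (onlyOne > 0)
    message(onlyOne, " reads present in only one alignment file; ",
            "treated as unmatched in the missing file")
  matchedNative <- universe %in% nat$matched
  matchedForeign <- universe %in% fon$matched
  DataFrame(read_id = universe,
            label = .labelFromMatches(matchedNative, matchedForeign))
}
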