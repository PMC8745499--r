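#' @include quantify.R
NULL

.exonsOverlap <- function(aStarts, aEnds, bStarts, bEnds) {
  any(outer(aStarts, bEnds, "<=") & outer(aEnds, bStarts, ">="))
}

#' Assign cuffcompare-style class codes
#'
#' Relates each candidate transcript to a reference annotation on the same
#' genome: `=` identical exon chain (same strand); `i` fully contained in a
#' reference intron (either strand); `x` exonic overlap on the opposite
#' strand; `e` single-exon candidate overlapping a reference exon and
#' extending into its flanking intron (pre-mRNA-like); `o` other partial
#' same-strand exonic overlap; `u` no overlap with any reference transcript
#' (intergenic); `other` for span overlap without exonic overlap that is not
#' intron containment. Precedence when several references apply:
#' `=` > `i` > `x` > same-strand exonic (`e`/`o`) > `u`.
#'
#' @param candidates [GenomicRanges::GRangesList] of candidate exon chains.
#' @param reference [GenomicRanges::GRangesList] of reference exon chains.
#' @param chromNames optional character vector of valid chromosome names; a
#'   candidate on a chromosome outside it raises a coordinate error.
#' @return character vector of class codes, named by candidate.
#' @export
assignClassCode <- function(candidates, reference, chromNames = NULL) {
  refChrom <- vapply(reference, function(g) as.character(seqnames(g)[1]), "")
  refStrand <- vapply(reference, function(g) as.character(strand(g)[1]), "")
  refStart <- lapply(reference, function(g) sort(start(g)))
  refEnd <- lapply(reference, function(g) sort(end(g)))
  out <- character(length(candidates))
  names(out) <- names(candidates)
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    chrom <- as.character(seqnames(cand)[1])
    if (!is.null(chromNames) && !chrom %in% chromNames)
      stop("coordinate error: candidate ",
           if (!is.null(names(candidates))) names(candidates)[ci] else ci,
           " lies on unknown chromosome ", chrom)
    cs <- sort(start(cand)); ce <- sort(end(cand))
    cstrand <- as.character(strand(cand)[1])
    span <- c(min(cs), max(ce))
    onChrom <- which(refChrom == chrom)
    code <- NA_character_
    anySpanOverlap <- FALSE
    sameStrandExonic <- integer()
    oppStrandExonic <- FALSE
    intronContained <- FALSE
    for (ri in onChrom) {
      rs <- refStart[[ri]]; re <- refEnd[[ri]]
      rspan <- c(rs[1], re[length(re)])
      if (span[2] < rspan[1] || span[1] > rspan[2]) next
      anySpanOverlap <- TRUE
      sameStrand <- refStrand[ri] == cstrand
      if (sameStrand && length(rs) == length(cs) &&
          all(rs == cs) && all(re == ce)) { code <- "="; break }
      # intron containment (either strand)
      if (length(rs) > 1) {
        is_ <- re[-length(re)] + 1L; ie_ <- rs[-1] - 1L
        if (any(is_ <= span[1] & ie_ >= span[2])) intronContained <- TRUE
      }
      if (.exonsOverlap(cs, ce, rs, re)) {
        if (sameStrand) sameStrandExonic <- c(sameStrandExonic, ri)
        else oppStrandExonic <- TRUE
      }
    }
    if (is.na(code)) {
      if (intronContained) code <- "i"
      else if (oppStrandExonic) code <- "x"
      else if (length(sameStrandExonic)) {
        code <- "o"
        if (length(cs) == 1) {
          # pre-mRNA-like: single exon reaching into a flanking intron
          for (ri in sameStrandExonic) {
            rs <- refStart[[ri]]; re <- refEnd[[ri]]
            if (length(rs) < 2) next
            is_ <- re[-length(re)] + 1L; ie_ <- rs[-1] - 1L
            if (.exonsOverlap(cs, ce, is_, ie_)) { code <- "e"; break }
          }
        }
      }
      else if (!anySpanOverlap) code <- "u"
      else code <- "other"
    }
    out[ci] <- code
  }
  out
}

#' Positional lncRNA classification
#'
#' Maps the class code of a filtered lncRNA to its positional type:
#' `u` -> lincRNA, `x` -> antisense, `i` -> intronic, `o`/`e` -> sense.
#' Codes `=` and `other` should have been removed by the filter cascade and
#' raise an error.
#'
#' @param classCodes character vector of class codes.
#' @return character vector of types.
#' @export
classifyLncrnaType <- function(classCodes) {
  map <- c(u = "lincRNA", x = "antisense", i = "intronic",
           o = "sense", e = "sense")
  bad <- setdiff(unique(classCodes), names(map))
  if (length(bad))
    stop("classification error: class code(s) ", paste(bad, collapse = ", "),
         " should have been filtered out")
  unname(map[classCodes])
}
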