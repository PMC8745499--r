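#' @include orf.R
NULL

#' ORF-based coding-potential test
#'
#' A transparent stand-in for published coding-potential tools: the longest
#' complete ORF (ATG..stop, stop included) is located by scanning the three
#' forward frames (the library protocol is strand-specific, so the sense
#' strand suffices; set `sixFrame = TRUE` for non-stranded data). The score
#' is `orf_coverage * log(longest_orf_length)` and a transcript is called
#' coding when the longest ORF reaches `orfMin` nt, when ORF coverage
#' reaches `coverageMin`, or when a user-supplied protein motif (regular
#' expression over the translated longest ORF) matches — the motif list
#' standing in for a protein-domain scan.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of spliced
#'   sequences over A/C/G/T/N (U is accepted and read as T).
#' @param orfMin coding call threshold on ORF length (nt), default 300.
#' @param coverageMin coding call threshold on ORF coverage, default 0.5.
#' @param motifs optional character vector of regular expressions matched
#'   against the translated longest ORF.
#' @param sixFrame also scan the reverse strand's three frames.
#' @return [S4Vectors::DataFrame] with `longest_orf_length`, `orf_coverage`,
#'   `score`, `is_coding`.
#' @export
codingPotential <- function(seqs, orfMin = 300L, coverageMin = 0.5,
                            motifs = NULL, sixFrame = FALSE) {
  seqs <- as.character(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence")
  seqs <- toupper(chartr("u", "t", seqs))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) stop("sequence contains characters outside {A,C,G,T,N}")
  n <- length(seqs)
  len <- integer(n); cov <- numeric(n); coding <- logical(n)
  for (i in seq_len(n)) {
    orf <- .forwardLongestOrf(seqs[i])
    strand <- "+"
    if (sixFrame) {
      rc <- .forwardLongestOrf(.revcomp(seqs[i]))
      if (rc$length > orf$length) { orf <- rc; strand <- "-" }
    }
    len[i] <- orf$length
    cov[i] <- orf$length / nchar(seqs[i])
    coding[i] <- orf$length >= orfMin || cov[i] >= coverageMin
    if (!coding[i] && length(motifs) && orf$length >= 6L) {
      s <- if (strand == "+") seqs[i] else .revcomp(seqs[i])
      pep <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, orf$start, orf$start + orf$length - 1L)),
        if.fuzzy.codon = "X"))
      coding[i] <- any(vapply(motifs, grepl, TRUE, x = pep))
    }
  }
  score <- ifelse(len > 0, cov * log(len), 0)
  DataFrame(longest_orf_length = len, orf_coverage = cov, score = score,
            is_coding = coding)
}
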