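#' @include AllClasses.R
NULL

# Longest ATG..stop ORF (stop inclusive) across the three forward frames of a
# DNA string. Returns nt length 0 when no complete ORF exists. Open-ended
# runs without a stop codon are not counted as ORFs.
.forwardLongestOrf <- function(seq) {
  n <- nchar(seq)
  best <- list(length = 0L, start = NA_integer_)
  if (n < 6) return(best)
  # numeric codon encoding: A=0 C=1 G=2 T=3, codon = 16a + 4b + c;
  # ATG = 14, stops TAA/TAG/TGA = 48/50/56; anything with N never matches
  v <- utf8ToInt(toupper(seq))
  code <- rep(-1e6L, n)
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  for (f in 0:2) {
    nc <- (n - f) %/% 3
    if (nc < 2) next
    i1 <- seq.int(1 + f, by = 3, length.out = nc)
    cod <- 16L * code[i1] + 4L * code[i1 + 1L] + code[i1 + 2L]
    atg <- which(cod == 14L)
    stp <- which(cod == 48L | cod == 50L | cod == 56L)
    if (!length(atg) || !length(stp)) next
    # first stop codon at or after each start
    idx <- findInterval(atg - 0.5, stp) + 1L
    ok <- idx <= length(stp)
    if (!any(ok)) next
    lens <- 3L * (stp[idx[ok]] - atg[ok] + 1L)
    w <- which.max(lens)
    if (lens[w] > best$length) {
      best$length <- lens[w]
      best$start <- i1[atg[ok][w]]
    }
  }
  best
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Longest ORF over all six frames (both strands); used as the brute-force
# biotype guard by the simulator.
.sixFrameLongestOrf <- function(seq) {
  max(.forwardLongestOrf(seq)$length, .forwardLongestOrf(.revcomp(seq))$length)
}
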