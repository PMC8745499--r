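#' @include methods.R
#' @useDynLib lncMobility, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Assignment parameters
#'
#' Parameters of the dual-genome read matcher: seed length `k`, the minimum
#' number of co-linear seed hits required before extension, and the maximum
#' tolerated mismatch fraction over the full-length alignment.
#'
#' @param k seed length in bp (>= 15 for genome-scale use; smaller values are
#'   accepted for toy references).
#' @param min_seed_hits minimum co-linear seed hits to attempt extension.
#' @param max_mismatch_rate tolerated mismatch fraction in `[0, 1)`.
#' @param mapq_floor minimum mapping quality when ingesting external SAM/BAM
#'   alignments.
#' @return a validated named list.
#' @export
assignmentParams <- function(k = 31L, min_seed_hits = 2L,
                             max_mismatch_rate = 0.05, mapq_floor = 1L) {
  stopifnot(k >= 2, min_seed_hits >= 1,
            max_mismatch_rate >= 0, max_mismatch_rate < 1, mapq_floor >= 0)
  list(k = as.integer(k), min_seed_hits = as.integer(min_seed_hits),
       max_mismatch_rate = max_mismatch_rate, mapq_floor = as.integer(mapq_floor))
}

#' Build a seed index over one species' reference
#'
#' Indexes every valid k-mer of the species' genomic chromosomes and of its
#' spliced transcript sequences under its canonical form (the
#' lexicographically smaller of the forward k-mer and its reverse
#' complement). Indexing the spliced transcripts makes the matcher
#' splice-aware: junction-spanning reads align full-length to a transcript
#' reference even though they cannot align contiguously to the genome.
#'
#' @param genomes a [GenomeSet].
#' @param species species label to index.
#' @param k seed length (2-31 bp).
#' @param includeTranscripts also index the spliced transcript sequences
#'   (default `TRUE`).
#' @return a [SeedIndex].
#' @export
buildSeedIndex <- function(genomes, species, k = 31L, includeTranscripts = TRUE) {
  g <- genomeSeq(genomes, species)
  if (all(Biostrings::width(g) < k))
    stop("empty index: k = ", k, " exceeds every chromosome of ", species)
  seqs <- as.character(g)
  names(seqs) <- names(g)
  isTx <- rep(0L, length(seqs))
  if (includeTranscripts) {
    tx <- splicedSeqs(genomes, species)
    tx <- tx[nchar(tx) >= k]
    seqs <- c(seqs, tx)
    isTx <- c(isTx, rep(1L, length(tx)))
  }
  ptr <- cpp_build_index(unname(seqs), names(seqs), isTx, as.integer(k))
  new("SeedIndex", species = species, k = as.integer(k), ptr = ptr,
      refNames = names(seqs))
}

#' Query a seed index for one k-mer
#'
#' Returns every indexed location of the canonical form of `kmer`; a k-mer
#' and its reverse complement therefore return identical locations (with
#' opposite strands).
#'
#' @param index a [SeedIndex].
#' @param kmer a string of length `k` over ACGT.
#' @return data.frame with columns `ref`, `pos` (1-based), `strand`.
#' @export
querySeedIndex <- function(index, kmer) {
  cpp_query_index(index@ptr, toupper(kmer))
}

#' Match reads against one species' reference
#'
#' A read matches when at least `min_seed_hits` co-linear canonical seed hits
#' on one reference/strand extend to a full-length alignment with mismatch
#' rate at most `max_mismatch_rate`. Degenerate bases (N) never match.
#' Presence/absence semantics with the best hit (fewest mismatches;
#' deterministic tie-break by reference order, then position) reported.
#'
#' @param reads character vector of read sequences.
#' @param index a [SeedIndex].
#' @param params an [assignmentParams()] list; its `k` must equal the
#'   index's.
#' @return [S4Vectors::DataFrame] with `matched`, `ref`, `pos`, `strand`,
#'   `mismatches`, `n_refs`, `ref_is_transcript`.
#' @export
matchGenome <- function(reads, index, params = assignmentParams()) {
  if (params$k != index@k)
    stop("params$k (", params$k, ") must equal the index k (", index@k, ")")
  if (any(nchar(reads) < index@k))
    stop("all reads must be at least k = ", index@k, " bases long")
  res <- cpp_match_reads(index@ptr, toupper(reads), params$min_seed_hits,
                         params$max_mismatch_rate)
  DataFrame(res)
}
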