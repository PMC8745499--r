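#' @include simConfig.R orf.R
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
NULL

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.NONSTOP_CODONS <- {
  cods <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)), .BASES, paste0))
  cods[!cods %in% c("TAA", "TAG", "TGA")]
}

.randDNA <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# Split total length into k parts, each >= minPart.
.splitLength <- function(total, k, minPart = 30L) {
  if (k == 1) return(total)
  if (total < k * minPart) stop("length too short to split into ", k, " exons")
  free <- total - k * minPart
  u <- runif(k)
  extra <- floor(u / sum(u) * free)
  extra[k] <- free - sum(extra[-k])
  as.integer(minPart + extra)
}

.simulateMrnaSeq <- function(L) {
  maxCod <- (L - 3L) %/% 3L
  totCod <- if (maxCod <= 102L) maxCod else sample(102L:maxCod, 1L)
  orfLen <- 3L * totCod
  s <- sample.int(L - orfLen + 1L, 1L)
  body <- paste(sample(.NONSTOP_CODONS, totCod - 2L, replace = TRUE), collapse = "")
  seq <- paste0(.randDNA(s - 1L), "ATG", body, sample(.STOPS, 1L),
                .randDNA(L - (s - 1L) - orfLen))
  list(seq = seq, orf_start = s, orf_end = s + orfLen - 1L)
}

.simulateLncSeq <- function(L, orfMax = 300L, covMax = 0.5) {
  for (i in seq_len(200L)) {
    seq <- .randDNA(L)
    fwd <- .forwardLongestOrf(seq)$length
    if (fwd >= orfMax || fwd / L >= covMax) next
    if (.forwardLongestOrf(.revcomp(seq))$length >= orfMax) next
    return(seq)
  }
  stop("failed to sample a non-coding sequence of length ", L,
       "; lower lncrna_len_mean or relax the ORF bound")
}

#' Simulate a divergent two-species genome pair with annotation
#'
#' Generates independent i.i.d.-uniform genomes for the parasite and the host
#' and places non-overlapping gene and lncRNA loci on both strands. Every
#' mRNA carries a complete ORF of at least 300 nt; every truth-lncRNA is
#' rejection-sampled until its longest ORF (all six frames) is below 300 nt
#' and its forward-frame ORF coverage is below 0.5, so the two biotypes are
#' separable by the package's coding-potential rule. Exon counts follow the
#' configured categorical distributions and spliced lengths a gamma
#' distribution around the configured means.
#'
#' @param config a [SimConfig].
#' @return a [GenomeSet] with species `"parasite"` and `"host"`.
#' @examples
#' gs <- generateGenomePair(simConfig(seed = 1, n_genes_per_species = 5,
#'                                    n_lncrnas_per_species = 3,
#'                                    genome_length_per_species = 120000L))
#' gs
#' @export
generateGenomePair <- function(config) {
  validObject(config)
  set.seed(.stageSeed(config, "genome"))
  genomes <- list()
  txRows <- list()
  exRows <- list()
  spliced <- character()
  for (sp in c("parasite", "host")) {
    res <- .simulateSpecies(sp, config)
    genomes[[sp]] <- res$genome
    txRows[[sp]] <- res$txData
    exRows[[sp]] <- res$exonTable
    spliced <- c(spliced, res$spliced)
  }
  td <- do.call(rbind, txRows)
  rownames(td) <- NULL
  et <- do.call(rbind, exRows)
  exn <- if (nrow(et)) {
    gr <- GRanges(et$chrom, IRanges(et$start, et$end), strand = et$strand)
    S4Vectors::split(gr, factor(et$transcript_id, levels = td$transcript_id))
  } else GRangesList()
  new("GenomeSet", genomes = genomes, exons = exn, txData = td,
      spliced = spliced)
}

.simulateSpecies <- function(sp, config) {
  G <- config@genome_length_per_species
  chrom <- paste0(sp, "_chr1")
  nG <- config@n_genes_per_species
  nL <- config@n_lncrnas_per_species
  n <- nG + nL
  biotype <- c(rep("mRNA", nG), rep("lncRNA-truth", nL))
  tx <- vector("list", n)
  for (i in seq_len(n)) {
    isM <- biotype[i] == "mRNA"
    meanLen <- if (isM) config@mrna_len_mean else config@lncrna_len_mean
    dist <- if (isM) config@mrna_exon_dist else config@lncrna_exon_dist
    k <- as.integer(sample(names(dist), 1L, prob = dist))
    L <- as.integer(round(rgamma(1L, shape = 6, scale = meanLen / 6)))
    floorLen <- max(if (isM) 640L else 250L, 40L * k, config@read_length + 10L)
    if (L < floorLen) L <- floorLen
    if (isM) {
      s <- .simulateMrnaSeq(L)
    } else {
      s <- list(seq = .simulateLncSeq(L), orf_start = NA_integer_,
                orf_end = NA_integer_)
    }
    exonLens <- .splitLength(L, k)
    intronLens <- if (k > 1) 60L + rgeom(k - 1L, 1 / 241) else integer()
    pieces <- character(2L * k - 1L)
    pieces[seq(1L, 2L * k - 1L, by = 2L)] <-
      substring(s$seq, cumsum(c(1L, exonLens[-k])),
                cumsum(exonLens))
    if (k > 1)
      pieces[seq(2L, 2L * k - 2L, by = 2L)] <-
        vapply(intronLens, .randDNA, character(1))
    tx[[i]] <- list(spliced = s$seq, pre = paste(pieces, collapse = ""),
                    exonLens = exonLens, intronLens = intronLens,
                    orf_start = s$orf_start, orf_end = s$orf_end,
                    strand = sample(c("+", "-"), 1L))
  }
  spans <- if (n) vapply(tx, function(t) nchar(t$pre), integer(1)) else integer()
  minGap <- 200L
  need <- sum(spans) + (n + 1L) * minGap
  if (need > G)
    stop("placement error: genome_length_per_species (", G,
         ") too short for the configured loci (need at least ", need, " bp)")
  ord <- if (n) sample.int(n) else integer()
  u <- runif(n + 1L)
  extra <- floor(u / sum(u) * (G - need))
  extra[n + 1L] <- (G - need) - sum(extra[-(n + 1L)])
  gaps <- as.integer(minGap + extra)
  pieces <- character(2L * n + 1L)
  locusStart <- integer(n)
  cursor <- 0L
  for (j in seq_len(n + 1L)) {
    pieces[2L * j - 1L] <- .randDNA(gaps[j])
    cursor <- cursor + gaps[j]
    if (j <= n) {
      i <- ord[j]
      locusStart[i] <- cursor + 1L
      ins <- if (tx[[i]]$strand == "+") tx[[i]]$pre else .revcomp(tx[[i]]$pre)
      pieces[2L * j] <- ins
      cursor <- cursor + spans[i]
    }
  }
  genomeStr <- paste(pieces, collapse = "")
  stopifnot(nchar(genomeStr) == G)
  genome <- Biostrings::DNAStringSet(genomeStr)
  names(genome) <- chrom

  ids <- if (n) sprintf("%s_%s_%04d", sp,
                        ifelse(biotype == "mRNA", "mrna", "lnc"),
                        c(seq_len(nG), seq_len(nL))) else character()
  exRows <- vector("list", n)
  splicedOut <- character(n)
  for (i in seq_len(n)) {
    t <- tx[[i]]
    k <- length(t$exonLens)
    # exon start offsets within the pre-RNA (transcript orientation)
    preOff <- cumsum(c(0L, head(t$exonLens, -1L) +
                         if (k > 1) t$intronLens else integer()))
    preLen <- spans[i]
    if (t$strand == "+") {
      gStart <- locusStart[i] + preOff
      gEnd <- gStart + t$exonLens - 1L
    } else {
      # transcript position p maps to genomic locusStart + preLen - p
      gEnd <- locusStart[i] + preLen - 1L - preOff
      gStart <- gEnd - t$exonLens + 1L
    }
    exRows[[i]] <- data.frame(transcript_id = ids[i], chrom = chrom,
                              start = gStart, end = gEnd, strand = t$strand,
                              stringsAsFactors = FALSE)
    splicedOut[i] <- t$spliced
  }
  names(splicedOut) <- ids
  td <- DataFrame(
    transcript_id = ids,
    gene_id = sub("_(mrna|lnc)_", "_gene_\\1_", ids),
    species = rep(sp, n), chrom = rep(chrom, n),
    strand = vapply(tx, `[[`, "", "strand"),
    biotype = biotype,
    spliced_length = unname(nchar(splicedOut)),
    orf_start = vapply(tx, function(t) as.integer(t$orf_start), 1L),
    orf_end = vapply(tx, function(t) as.integer(t$orf_end), 1L))
  et <- if (n) do.call(rbind, exRows) else
    data.frame(transcript_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  list(genome = genome, txData = td, exonTable = et, spliced = splicedOut)
}
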