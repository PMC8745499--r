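#' @include librarySim.R
#' @importFrom rtracklayer export import
NULL

.annotationGRanges <- function(genomes, sp) {
  td <- txData(genomes)
  td <- td[td$species == sp, , drop = FALSE]
  if (!nrow(td)) return(GRanges())
  ex <- transcriptExons(genomes)[td$transcript_id]
  spans <- unlist(range(ex))
  txGr <- GRanges(td$chrom, IRanges(GenomicRanges::start(spans),
                                    GenomicRanges::end(spans)),
                  strand = td$strand)
  S4Vectors::mcols(txGr) <- DataFrame(
    type = "transcript", ID = td$transcript_id, Parent = NA_character_,
    gene_id = td$gene_id, biotype = td$biotype)
  exGr <- unlist(ex, use.names = FALSE)
  nper <- lengths(ex)
  S4Vectors::mcols(exGr) <- DataFrame(
    type = "exon",
    ID = paste0(rep(td$transcript_id, nper), ".e",
                unlist(lapply(nper, seq_len))),
    Parent = rep(td$transcript_id, nper),
    gene_id = rep(td$gene_id, nper),
    biotype = rep(td$biotype, nper))
  c(txGr, exGr)
}

#' Write a simulated system to disk
#'
#' Writes one genome FASTA and one GFF3 annotation per species (transcript
#' and exon features, biotype in the attributes), paired FASTQ files per
#' tissue and a tab-separated truth table
#' (`read_id`, `tissue`, `truth_species`, `truth_transcript_id`,
#' `truth_spliced`). Identical configurations produce byte-identical files.
#'
#' @param sim result of [simulateParasiteSystem()] (or a list with `genomes`
#'   and `libraries`).
#' @param dir output directory, created if needed.
#' @param gzip compress the FASTQ files.
#' @return invisibly, the vector of paths written.
#' @export
writeSimulation <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- sim$genomes
  paths <- character()
  for (sp in speciesNames(genomes)) {
    fa <- file.path(dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(genomeSeq(genomes, sp), fa)
    gff <- file.path(dir, paste0(sp, ".gff3"))
    rtracklayer::export(.annotationGRanges(genomes, sp), gff, format = "gff3")
    paths <- c(paths, fa, gff)
  }
  truth <- list()
  for (tissue in names(sim$libraries$reads)) {
    rd <- sim$libraries$reads[[tissue]]
    for (mate in 1:2) {
      seqs <- Biostrings::DNAStringSet(rd[[paste0("mate", mate)]])
      names(seqs) <- paste0(rd$read_id, "/", mate)
      fq <- file.path(dir, paste0(tissue, "_R", mate, ".fastq",
                                  if (gzip) ".gz" else ""))
      quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
      Biostrings::writeXStringSet(seqs, fq, format = "fastq",
                                  qualities = quals,
                                  compress = gzip)
      paths <- c(paths, fq)
    }
    truth[[tissue]] <- as.data.frame(rd[, c("read_id", "tissue",
                                            "truth_species",
                                            "truth_transcript_id",
                                            "truth_spliced")])
  }
  tt <- file.path(dir, "truth.tsv")
  utils::write.table(do.call(rbind, truth), tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, tt)
  invisible(paths)
}

#' Load a genome pair and annotation from FASTA/GFF3 files
#'
#' Real-data entry point mirroring the simulated [GenomeSet]: one genome
#' FASTA and one GFF3 per species. Transcript features are rows with a
#' `transcript`-like type; exons are linked by `Parent`. A `biotype`
#' attribute is honoured when present, otherwise transcripts are loaded as
#' `candidate`.
#'
#' @param fastaFiles named character vector of FASTA paths, names are species
#'   labels.
#' @param gffFiles named character vector of GFF3 paths, same names.
#' @return a [GenomeSet].
#' @export
genomeSetFromFiles <- function(fastaFiles, gffFiles) {
  stopifnot(identical(sort(names(fastaFiles)), sort(names(gffFiles))))
  genomes <- list()
  rows <- list()
  exons <- list()
  spliced <- character()
  for (sp in names(fastaFiles)) {
    g <- Biostrings::readDNAStringSet(fastaFiles[[sp]])
    names(g) <- sub("\\s.*", "", names(g))
    genomes[[sp]] <- g
    gff <- rtracklayer::import(gffFiles[[sp]], format = "gff3")
    isTx <- tolower(as.character(gff$type)) %in%
      c("transcript", "mrna", "lnc_rna", "lncrna")
    txGr <- gff[isTx]
    exGr <- gff[tolower(as.character(gff$type)) == "exon"]
    parent <- as.character(S4Vectors::unstrsplit(exGr$Parent, ","))
    exBy <- split(exGr, parent)
    ids <- as.character(txGr$ID)
    exBy <- exBy[ids[ids %in% names(exBy)]]
    biotype <- if (!is.null(txGr$biotype)) as.character(txGr$biotype)
               else rep("candidate", length(txGr))
    geneId <- if (!is.null(txGr$gene_id)) as.character(txGr$gene_id) else ids
    keep <- ids %in% names(exBy)
    # order exons 5'->3' within each transcript
    ord <- lapply(seq_along(exBy), function(i) {
      gr <- exBy[[i]]
      o <- order(GenomicRanges::start(gr),
                 decreasing = as.character(GenomicRanges::strand(gr)[1]) == "-")
      gr[o]
    })
    names(ord) <- names(exBy)
    for (i in which(keep)) {
      id <- ids[i]
      gr <- ord[[id]]
      sq <- Biostrings::extractAt(
        g[[as.character(GenomicRanges::seqnames(gr)[1])]],
        IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)))
      sq <- Biostrings::DNAStringSet(sq)
      # gr is already in transcript (5'->3') order; on the minus strand each
      # exon's sequence is the reverse complement of its genomic slice
      if (as.character(GenomicRanges::strand(gr)[1]) == "-")
        sq <- Biostrings::reverseComplement(sq)
      spliced[id] <- paste(as.character(sq), collapse = "")
      exons[[id]] <- ord[[id]]
      rows[[id]] <- DataFrame(
        transcript_id = id, gene_id = geneId[i], species = sp,
        chrom = as.character(GenomicRanges::seqnames(gr)[1]),
        strand = as.character(GenomicRanges::strand(gr)[1]),
        biotype = biotype[i],
        spliced_length = sum(GenomicRanges::width(gr)),
        orf_start = NA_integer_, orf_end = NA_integer_)
    }
  }
  td <- do.call(rbind, unname(rows))
  new("GenomeSet", genomes = genomes, exons = GRangesList(exons)[td$transcript_id],
      txData = td, spliced = spliced)
}
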