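#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom GenomicRanges GRangesList
#' @importFrom Biostrings DNAStringSet
NULL

#' Simulation configuration for a two-species parasitic transcriptome
#'
#' Holds every tunable of the synthetic-data generator: genome and catalog
#' sizes, exon-count and length distributions for lncRNAs and mRNAs, library
#' sizes, per-tissue mobile-read fractions, the abundance-mobility coupling
#' exponent and the sequencing error rate. Construct with [simConfig()].
#'
#' @slot seed integer root RNG seed; per-stage child seeds are derived from it.
#' @slot genome_length_per_species genome length in bp for each species.
#' @slot n_genes_per_species number of protein-coding genes per species.
#' @slot n_lncrnas_per_species number of lncRNA loci per species.
#' @slot lncrna_exon_dist named numeric, categorical distribution over exon
#'   counts for lncRNAs (names are exon counts, values sum to 1).
#' @slot mrna_exon_dist categorical distribution over exon counts for mRNAs.
#' @slot lncrna_len_mean mean spliced length (bp) of lncRNAs.
#' @slot mrna_len_mean mean spliced length (bp) of mRNAs.
#' @slot read_length read length in bp.
#' @slot n_read_pairs_per_tissue read pairs simulated per tissue library.
#' @slot mobile_fraction_parasite_to_host fraction of host-stem reads drawn
#'   from parasite transcripts.
#' @slot mobile_fraction_host_to_parasite fraction of parasite-stem reads
#'   drawn from host transcripts.
#' @slot interface_mix fraction of interface reads originating from the
#'   parasite.
#' @slot abundance_mobility_bias exponent coupling transcript abundance to
#'   mobility propensity.
#' @slot error_rate per-base substitution probability.
#' @slot unspliced_fraction probability that a native read is drawn from the
#'   unspliced pre-RNA rather than the mature transcript.
#' @slot mobile_pool_fraction fraction of a species' transcripts eligible to
#'   move (the abundance-biased mobile pool).
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer",
  genome_length_per_species = "integer",
  n_genes_per_species = "integer",
  n_lncrnas_per_species = "integer",
  lncrna_exon_dist = "numeric",
  mrna_exon_dist = "numeric",
  lncrna_len_mean = "numeric",
  mrna_len_mean = "numeric",
  read_length = "integer",
  n_read_pairs_per_tissue = "integer",
  mobile_fraction_parasite_to_host = "numeric",
  mobile_fraction_host_to_parasite = "numeric",
  interface_mix = "numeric",
  abundance_mobility_bias = "numeric",
  error_rate = "numeric",
  unspliced_fraction = "numeric",
  mobile_pool_fraction = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  frac <- c(
    mobile_fraction_parasite_to_host = object@mobile_fraction_parasite_to_host,
    mobile_fraction_host_to_parasite = object@mobile_fraction_host_to_parasite,
    interface_mix = object@interface_mix,
    error_rate = object@error_rate,
    unspliced_fraction = object@unspliced_fraction,
    mobile_pool_fraction = object@mobile_pool_fraction
  )
  bad <- names(frac)[frac < 0 | frac > 1 | is.na(frac)]
  if (length(bad))
    msg <- c(msg, paste0("fractions must lie in [0,1]: ", paste(bad, collapse = ", ")))
  for (nm in c("lncrna_exon_dist", "mrna_exon_dist")) {
    d <- slot(object, nm)
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8)
      msg <- c(msg, paste0(nm, " must be non-negative and sum to 1"))
    if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d)))))
      msg <- c(msg, paste0(nm, " must be named by integer exon counts"))
  }
  if (object@genome_length_per_species < 1000)
    msg <- c(msg, "genome_length_per_species must be at least 1000 bp")
  if (object@read_length < 20)
    msg <- c(msg, "read_length must be at least 20 bp")
  if (object@n_genes_per_species < 0 || object@n_lncrnas_per_species < 0)
    msg <- c(msg, "catalog sizes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Two-species genome pair with transcript annotation
#'
#' The simulated (or loaded) reference for a parasitic system: one genome
#' sequence set per species label plus a transcript catalog. Exons are stored
#' 1-based closed (GFF3 convention).
#'
#' @slot genomes named list of [Biostrings::DNAStringSet], one per species.
#' @slot exons named [GenomicRanges::GRangesList], exons per transcript in
#'   5'->3' transcript order; names are transcript ids.
#' @slot txData [S4Vectors::DataFrame] with one row per transcript:
#'   `transcript_id`, `gene_id`, `species`, `chrom`, `strand`, `biotype`
#'   (`mRNA`, `lncRNA-truth` or `candidate`), `spliced_length`, `orf_start`,
#'   `orf_end` (spliced coordinates, `NA` when absent).
#' @slot spliced named character vector of spliced (mature) sequences.
#' @exportClass GenomeSet
setClass("GenomeSet", representation(
  genomes = "list",
  exons = "GRangesList",
  txData = "DFrame",
  spliced = "character"
))

setValidity("GenomeSet", function(object) {
  msg <- character()
  if (is.null(names(object@genomes)) || anyDuplicated(names(object@genomes)))
    msg <- c(msg, "genomes must be a named list with distinct species labels")
  td <- object@txData
  need <- c("transcript_id", "gene_id", "species", "chrom", "strand",
            "biotype", "spliced_length")
  if (!all(need %in% colnames(td)))
    msg <- c(msg, paste("txData must contain columns:", paste(need, collapse = ", ")))
  if (nrow(td) && !all(td$species %in% names(object@genomes)))
    msg <- c(msg, "every transcript's species must be a genome label")
  if (nrow(td) && !identical(sort(names(object@exons)), sort(td$transcript_id)))
    msg <- c(msg, "exons must be keyed by the transcript ids in txData")
  if (length(msg)) msg else TRUE
})

#' Seed index over one species' reference
#'
#' A canonical k-mer index over a species' genomic chromosomes plus its
#' spliced transcript sequences (so junction-spanning reads are matchable).
#' Built with [buildSeedIndex()]; the external pointer is session-local.
#'
#' @slot species species label the index was built for.
#' @slot k seed length in bp.
#' @slot ptr external pointer to the C++ index.
#' @slot refNames names of the indexed reference sequences.
#' @exportClass SeedIndex
setClass("SeedIndex", representation(
  species = "character",
  k = "integer",
  ptr = "externalptr",
  refNames = "character"
))

#' Per-library read assignment summary
#'
#' The outcome of classifying every read pair of one tissue library against
#' the native and foreign genomes: native / mobile / filtered tallies, the
#' foreign-read proportion mobile/(mobile+native), a conflict count
#' (mates matching opposite genomes exclusively), and the per-fragment label
#' table with best-hit locations.
#'
#' @slot tissue tissue label.
#' @slot counts named numeric: `native`, `mobile`, `filtered`.
#' @slot conflicts number of mate-conflict pairs (included in `filtered`).
#' @slot labels [S4Vectors::DataFrame], one row per fragment.
#' @exportClass AssignmentSummary
setClass("AssignmentSummary", representation(
  tissue = "character",
  counts = "numeric",
  conflicts = "numeric",
  labels = "DFrame"
))

setValidity("AssignmentSummary", function(object) {
  msg <- character()
  if (!all(c("native", "mobile", "filtered") %in% names(object@counts)))
    msg <- c(msg, "counts must be named native/mobile/filtered")
  if (nrow(object@labels) &&
      sum(object@counts) != nrow(object@labels))
    msg <- c(msg, "native + mobile + filtered must equal the number of fragments")
  if (length(msg)) msg else TRUE
})

#' Mobility tally table
#'
#' Counts of mobile and non-mobile transcripts per (species, biotype) cell.
#' Percentages are always recomputed from the counts (see
#' [mobilityPercentages()]), never stored.
#'
#' @slot counts numeric matrix with rows `mobile`, `nonmobile`, `total` and
#'   one column per (species, biotype) combination.
#' @slot species character vector, species per column.
#' @slot biotype character vector, biotype per column.
#' @exportClass MobilityTable
setClass("MobilityTable", representation(
  counts = "matrix",
  species = "character",
  biotype = "character"
))

setValidity("MobilityTable", function(object) {
  m <- object@counts
  msg <- character()
  if (!all(c("mobile", "nonmobile", "total") %in% rownames(m)))
    msg <- c(msg, "counts must have rows mobile/nonmobile/total")
  else if (any(m["mobile", ] + m["nonmobile", ] != m["total", ]))
    msg <- c(msg, "mobile + nonmobile must equal total in every cell")
  if (length(object@species) != ncol(m) || length(object@biotype) != ncol(m))
    msg <- c(msg, "species/biotype must have one entry per column")
  if (length(msg)) msg else TRUE
})
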