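#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("genomeSeq", "GenomeSet", function(x, species) {
  if (!species %in% names(x@genomes))
    stop("unknown species label: ", species)
  x@genomes[[species]]
})

#' @rdname accessors
setMethod("speciesNames", "GenomeSet", function(x) names(x@genomes))

#' @rdname accessors
setMethod("txData", "GenomeSet", function(x) x@txData)

#' @rdname accessors
setMethod("transcriptExons", "GenomeSet", function(x) x@exons)

#' @rdname accessors
setMethod("splicedSeqs", "GenomeSet", function(x, species) {
  if (missing(species)) return(x@spliced)
  x@spliced[x@txData$transcript_id[x@txData$species == species]]
})

#' @rdname accessors
setMethod("readLabels", "AssignmentSummary", function(x) x@labels)

#' @rdname accessors
setMethod("assignmentCounts", "AssignmentSummary", function(x) x@counts)

#' @rdname accessors
setMethod("conflictCount", "AssignmentSummary", function(x) x@conflicts)

#' @rdname accessors
setMethod("mobilityCounts", "MobilityTable", function(x) x@counts)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  genome length/species:", object@genome_length_per_species, "bp\n")
  cat("  catalog/species:", object@n_genes_per_species, "mRNA genes,",
      object@n_lncrnas_per_species, "lncRNA loci\n")
  cat("  mean spliced length: lncRNA", object@lncrna_len_mean, "bp, mRNA",
      object@mrna_len_mean, "bp\n")
  cat("  libraries:", object@n_read_pairs_per_tissue, "pairs/tissue, read length",
      object@read_length, "bp, error rate", object@error_rate, "\n")
  cat("  mobile fractions: parasite->host", object@mobile_fraction_parasite_to_host,
      ", host->parasite", object@mobile_fraction_host_to_parasite, "\n")
  cat("  abundance-mobility bias:", object@abundance_mobility_bias, "\n")
})

setMethod("show", "GenomeSet", function(object) {
  cat("GenomeSet with", length(object@genomes), "species:",
      paste(names(object@genomes), collapse = ", "), "\n")
  for (sp in names(object@genomes)) {
    n <- sum(object@txData$species == sp)
    cat("  ", sp, ": ", sum(lengths(object@genomes[[sp]])), " bp, ",
        n, " transcripts\n", sep = "")
  }
})

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex (k=", object@k, ") for species '", object@species, "': ",
      length(object@refNames), " reference sequences\n", sep = "")
})

setMethod("show", "AssignmentSummary", function(object) {
  cat("AssignmentSummary [", object@tissue, "]\n", sep = "")
  print(object@counts)
  cat("  mate conflicts:", object@conflicts, "\n")
  cat("  foreign-read proportion:",
      format(foreignReadProportion(object), digits = 4), "\n")
})

setMethod("show", "MobilityTable", function(object) {
  cat("MobilityTable\n")
  m <- object@counts
  colnames(m) <- paste(object@species, object@biotype, sep = ":")
  print(m)
  pct <- mobilityPercentages(object)$mobile_pct
  cat("mobile %:", paste(sprintf("%s=%s", colnames(m), pct$mobile_pct),
                         collapse = " "), "\n")
})

#' Foreign-read proportion of a library
#'
#' The proportion of reads assigned to the foreign genome among all
#' genome-matched reads, mobile / (mobile + native). For an empty library or
#' one with no matched reads the proportion is undefined and `NA` is returned
#' (never 0).
#'
#' @param x an [AssignmentSummary].
#' @param ... unused.
#' @return a single numeric value, or `NA` when undefined.
#' @export
#' @rdname foreignReadProportion
setMethod("foreignReadProportion", "AssignmentSummary", function(x, ...) {
  denom <- x@counts[["mobile"]] + x@counts[["native"]]
  if (denom == 0) return(NA_real_)
  x@counts[["mobile"]] / denom
})
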