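#' @include AllClasses.R
NULL

#' Build a simulation configuration
#'
#' Defaults encode the conditions of the parasite-host system the simulator
#' emulates: 55% of lncRNAs have two exons, mean spliced lengths of
#' 1458 bp (lncRNA) and 2133 bp (mRNA), 2x150 bp strand-specific reads, and
#' per-stem foreign-read fractions of 1.5% (parasite into host) and 0.17%
#' (host into parasite). Mobility propensity scales with transcript abundance
#' raised to `abundance_mobility_bias`.
#'
#' @param seed integer root seed; all per-stage streams derive from it.
#' @param genome_length_per_species genome length per species (bp).
#' @param n_genes_per_species protein-coding genes per species.
#' @param n_lncrnas_per_species lncRNA loci per species.
#' @param lncrna_exon_dist named probabilities over lncRNA exon counts.
#' @param mrna_exon_dist named probabilities over mRNA exon counts.
#' @param lncrna_len_mean mean lncRNA spliced length (bp).
#' @param mrna_len_mean mean mRNA spliced length (bp).
#' @param read_length read length (bp).
#' @param n_read_pairs_per_tissue read pairs per tissue library.
#' @param mobile_fraction_parasite_to_host fraction of host-stem reads of
#'   parasite origin.
#' @param mobile_fraction_host_to_parasite fraction of parasite-stem reads of
#'   host origin.
#' @param interface_mix fraction of interface reads from the parasite.
#' @param abundance_mobility_bias abundance exponent of mobility propensity.
#' @param error_rate per-base substitution probability.
#' @param unspliced_fraction probability a native read comes from pre-RNA.
#' @param mobile_pool_fraction fraction of transcripts eligible to move.
#' @return a validated [SimConfig] object.
#' @examples
#' cfg <- simConfig(seed = 1, n_genes_per_species = 20,
#'                  n_lncrnas_per_species = 10,
#'                  genome_length_per_species = 300000L)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      genome_length_per_species = 2000000L,
                      n_genes_per_species = 150L,
                      n_lncrnas_per_species = 60L,
                      lncrna_exon_dist = c("1" = 0.15, "2" = 0.55,
                                           "3" = 0.20, "4" = 0.10),
                      mrna_exon_dist = c("1" = 0.05, "2" = 0.10, "3" = 0.15,
                                         "4" = 0.15, "5" = 0.15, "6" = 0.12,
                                         "7" = 0.10, "8" = 0.08, "9" = 0.05,
                                         "10" = 0.05),
                      lncrna_len_mean = 1458,
                      mrna_len_mean = 2133,
                      read_length = 150L,
                      n_read_pairs_per_tissue = 20000L,
                      mobile_fraction_parasite_to_host = 0.015,
                      mobile_fraction_host_to_parasite = 0.0017,
                      interface_mix = 0.5,
                      abundance_mobility_bias = 1,
                      error_rate = 0.001,
                      unspliced_fraction = 0.05,
                      mobile_pool_fraction = 0.1) {
  new("SimConfig",
      seed = as.integer(seed),
      genome_length_per_species = as.integer(genome_length_per_species),
      n_genes_per_species = as.integer(n_genes_per_species),
      n_lncrnas_per_species = as.integer(n_lncrnas_per_species),
      lncrna_exon_dist = lncrna_exon_dist,
      mrna_exon_dist = mrna_exon_dist,
      lncrna_len_mean = lncrna_len_mean,
      mrna_len_mean = mrna_len_mean,
      read_length = as.integer(read_length),
      n_read_pairs_per_tissue = as.integer(n_read_pairs_per_tissue),
      mobile_fraction_parasite_to_host = mobile_fraction_parasite_to_host,
      mobile_fraction_host_to_parasite = mobile_fraction_host_to_parasite,
      interface_mix = interface_mix,
      abundance_mobility_bias = abundance_mobility_bias,
      error_rate = error_rate,
      unspliced_fraction = unspliced_fraction,
      mobile_pool_fraction = mobile_pool_fraction)
}

# Deterministic child seed per stage, kept below 2^31.
.stageSeed <- function(config, stage) {
  offs <- c(genome = 11L, expression = 101L, libraries = 1009L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (config@seed %% 100000L) * 17477L + offs[[stage]]
}
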