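test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simConfig(mobile_fraction_parasite_to_host = 1.2), "fractions")
  expect_error(simConfig(error_rate = -0.1), "fractions")
  expect_error(simConfig(lncrna_exon_dist = c("1" = 0.5, "2" = 0.4)),
               "sum to 1")
  expect_s4_class(simConfig(), "SimConfig")
})

test_that("identical configurations give identical simulations, to the byte", {
  cfg <- smallConfig(seed = 42L, n_read_pairs_per_tissue = 200L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  p1 <- writeSimulation(simulateParasiteSystem(cfg), d1)
  p2 <- writeSimulation(simulateParasiteSystem(cfg), d2)
  expect_equal(basename(p1), basename(p2))
  for (i in seq_along(p1))
    expect_identical(unname(tools::md5sum(p1[i])), unname(tools::md5sum(p2[i])),
                     label = basename(p1[i]))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty catalog still yields a valid genome pair", {
  cfg <- simConfig(seed = 2L, n_genes_per_species = 0L,
                   n_lncrnas_per_species = 0L,
                   genome_length_per_species = 50000L)
  gs <- generateGenomePair(cfg)
  expect_true(validObject(gs))
  expect_equal(nrow(txData(gs)), 0)
  expect_equal(sum(Biostrings::width(genomeSeq(gs, "parasite"))), 50000)
})

test_that("infeasible locus placement raises an error naming the genome length", {
  cfg <- simConfig(seed = 3L, n_genes_per_species = 50L,
                   n_lncrnas_per_species = 0L,
                   genome_length_per_species = 10000L)
  expect_error(generateGenomePair(cfg), "genome_length_per_species")
})

test_that("simulated biotypes are separated by ORF content", {
  gs <- smallSystem()$sim$genomes
  td <- txData(gs)
  spl <- splicedSeqs(gs)
  for (id in td$transcript_id[td$biotype == "lncRNA-truth"]) {
    expect_lt(max(oracleLongestOrf(spl[[id]]),
                  oracleLongestOrf(oracleRevcomp(spl[[id]]))), 300)
  }
  for (id in td$transcript_id[td$biotype == "mRNA"])
    expect_gte(oracleLongestOrf(spl[[id]]), 300)
})

test_that("exon chains are consistent with the genome and spliced sequences", {
  gs <- smallSystem()$sim$genomes
  td <- txData(gs)
  ex <- transcriptExons(gs)
  for (i in sample(nrow(td), 12)) {
    id <- td$transcript_id[i]
    gr <- ex[[id]]
    g <- genomeSeq(gs, td$species[i])[[td$chrom[i]]]
    sq <- Biostrings::DNAStringSet(Biostrings::extractAt(
      g, IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr))))
    if (td$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
    expect_identical(paste(as.character(sq), collapse = ""),
                     unname(splicedSeqs(gs)[id]))
    # exons sorted and non-overlapping in genomic coordinates
    st <- sort(GenomicRanges::start(gr)); en <- sort(GenomicRanges::end(gr))
    if (length(st) > 1) expect_true(all(st[-1] > en[-length(en)]))
  }
})

test_that("exon-count and length distributions match the configured study values", {
  gs <- bigLncCatalog()
  td <- txData(gs)
  lnc <- td[td$species == "parasite" & td$biotype == "lncRNA-truth", ]
  nex <- lengths(transcriptExons(gs)[lnc$transcript_id])
  p2 <- mean(nex == 2)
  sigma <- sqrt(0.55 * 0.45 / length(nex))
  expect_lt(abs(p2 - 0.55), 3 * sigma)
  expect_lt(abs(mean(lnc$spliced_length) - 1458) / 1458, 0.05)
})

test_that("abundance bias couples mobility to expression", {
  # large catalog (2000 transcripts in the mobile species) for power
  gs <- bigLncCatalog()
  td <- txData(gs)
  cfg0 <- smallConfig(seed = 7L, abundance_mobility_bias = 0)
  e0 <- simulateExpression(gs, cfg0)
  # exponent zero: propensity flat, so mobility is uncorrelated with abundance
  ids <- td$transcript_id[td$species == "parasite"]
  expect_lt(stats::sd(e0$propensity[ids]), 1e-12)
  expect_gt(stats::cor.test(e0$abundance[ids],
                            as.numeric(ids %in% e0$mobile_pool$parasite),
                            method = "spearman", exact = FALSE)$p.value, 0.01)
  cfg1 <- smallConfig(seed = 7L, abundance_mobility_bias = 1)
  e1 <- simulateExpression(gs, cfg1)
  mob <- e1$mobile_pool$parasite
  non <- setdiff(ids, mob)
  expect_gt(length(mob), 0)
  wt <- stats::wilcox.test(e1$abundance[mob], e1$abundance[non],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  # zero mobile fraction leaves the pool empty
  eZ <- simulateExpression(gs, smallConfig(
    seed = 7L, mobile_fraction_parasite_to_host = 0))
  expect_length(eZ$mobile_pool$parasite, 0)
})

test_that("libraries conserve read counts and record consistent truth", {
  sys <- smallSystem()
  libs <- sys$sim$libraries
  td <- txData(sys$sim$genomes)
  for (tissue in names(libs$reads)) {
    rd <- libs$reads[[tissue]]
    expect_equal(nrow(rd) + libs$skipped[[tissue]],
                 sys$cfg@n_read_pairs_per_tissue)
    expect_true(all(rd$truth_transcript_id %in% td$transcript_id))
    expect_true(all(td$species[match(rd$truth_transcript_id,
                                     td$transcript_id)] == rd$truth_species))
    expect_true(all(nchar(rd$mate1) == sys$cfg@read_length))
    expect_true(all(nchar(rd$mate2) == sys$cfg@read_length))
  }
  # mobile molecules travel as mature RNA: every foreign-origin read is a
  # substring of the spliced sequence, never of intronic context
  spl <- splicedSeqs(sys$sim$genomes)
  hs <- libs$reads$host_stem
  foreign <- which(hs$truth_species == "parasite")
  expect_gt(length(foreign), 0)
  expect_true(all(hs$truth_spliced[foreign]))
  for (i in foreign) {
    tplt <- spl[[hs$truth_transcript_id[i]]]
    expect_true(grepl(hs$mate1[i], tplt, fixed = TRUE))
  }
})

test_that("a mean Poisson-scale binomial draw recovers the mobile read fraction", {
  cfg <- simConfig(seed = 3L, n_genes_per_species = 20L,
                   n_lncrnas_per_species = 10L,
                   genome_length_per_species = 400000L,
                   n_read_pairs_per_tissue = 100000L, error_rate = 0,
                   mobile_fraction_parasite_to_host = 0.015)
  sim <- simulateParasiteSystem(cfg)
  hs <- sim$libraries$reads$host_stem
  frac <- mean(hs$truth_species == "parasite")
  sigma <- sqrt(0.015 * 0.985 / nrow(hs))
  expect_lt(abs(frac - 0.015), 3 * sigma)
})
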