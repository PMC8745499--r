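# Shared fixtures. Expensive simulations are memoized so several test files
# can reuse them without re-simulating.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

smallConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes_per_species = 20L,
               n_lncrnas_per_species = 10L,
               genome_length_per_species = 400000L,
               n_read_pairs_per_tissue = 2000L, error_rate = 0)
  do.call(simConfig, utils::modifyList(args, list(...)))
}

# small clean-divergence system with assignment, shared across files
smallSystem <- function() {
  memo("smallSystem", {
    cfg <- smallConfig()
    sim <- simulateParasiteSystem(cfg)
    ip <- buildSeedIndex(sim$genomes, "parasite")
    ih <- buildSeedIndex(sim$genomes, "host")
    sPar <- assignLibrary(sim$libraries$reads$parasite_stem, ip, ih)
    sHost <- assignLibrary(sim$libraries$reads$host_stem, ih, ip)
    sInt <- assignInterfaceLibrary(sim$libraries$reads$interface, ip, ih)
    cr <- countFragments(list(parasite_stem = sPar, interface = sInt,
                              host_stem = sHost), sim$genomes,
                         readLength = cfg@read_length)
    se <- computeFpkm(cr, sim$genomes)
    list(cfg = cfg, sim = sim, ip = ip, ih = ih,
         summaries = list(parasite_stem = sPar, interface = sInt,
                          host_stem = sHost),
         counts = cr, se = se)
  })
}

# 2000-lncRNA catalog at default length/exon settings, for distribution tests
bigLncCatalog <- function() {
  memo("bigLncCatalog", {
    cfg <- simConfig(seed = 11L, n_genes_per_species = 0L,
                     n_lncrnas_per_species = 2000L,
                     genome_length_per_species = 5000000L)
    generateGenomePair(cfg)
  })
}

# hand-built GenomeSet: `txs` is a list of lists with fields id, species,
# chrom, strand, starts, ends (exon coordinates, 5'->3' transcript order is
# derived from strand), biotype
manualGenomeSet <- function(chromSeqs, txs, species = NULL) {
  if (is.null(species)) species <- unique(vapply(txs, `[[`, "", "species"))
  genomes <- lapply(stats::setNames(nm = species), function(sp) {
    keep <- vapply(chromSeqs$species, identical, TRUE, sp)
    g <- Biostrings::DNAStringSet(unlist(chromSeqs$seq[keep]))
    names(g) <- unlist(chromSeqs$chrom[keep])
    g
  })
  exList <- list()
  rows <- list()
  spliced <- character()
  for (t in txs) {
    o <- order(t$starts, decreasing = t$strand == "-")
    gr <- GenomicRanges::GRanges(t$chrom,
                                 IRanges::IRanges(t$starts[o], t$ends[o]),
                                 strand = t$strand)
    exList[[t$id]] <- gr
    g <- genomes[[t$species]][[t$chrom]]
    if (max(t$ends) <= length(g)) {
      sq <- Biostrings::DNAStringSet(Biostrings::extractAt(
        g, IRanges::IRanges(t$starts[o], t$ends[o])))
      if (t$strand == "-") sq <- Biostrings::reverseComplement(sq)
      spliced[t$id] <- paste(as.character(sq), collapse = "")
    } else {
      # coordinate-only fixture: sequence content not needed
      spliced[t$id] <- ""
    }
    rows[[t$id]] <- S4Vectors::DataFrame(
      transcript_id = t$id, gene_id = t$id, species = t$species,
      chrom = t$chrom, strand = t$strand,
      biotype = if (is.null(t$biotype)) "candidate" else t$biotype,
      spliced_length = sum(t$ends - t$starts + 1L),
      orf_start = NA_integer_, orf_end = NA_integer_)
  }
  td <- do.call(rbind, unname(rows))
  new("GenomeSet", genomes = genomes,
      exons = GenomicRanges::GRangesList(exList)[td$transcript_id],
      txData = td, spliced = spliced)
}

# reference tally of a soybean-dodder parasitic system, used as a fixture:
# counts are inputs, every percentage is recomputed
table1Fixture <- function() {
  catalog <- data.frame(
    transcript_id = c(sprintf("dlnc%04d", 1:4688), sprintf("dmrna%05d", 1:16977),
                      sprintf("slnc%04d", 1:1892), sprintf("smrna%05d", 1:42296)),
    species = rep(c("parasite", "parasite", "host", "host"),
                  c(4688, 16977, 1892, 42296)),
    biotype = rep(c("lncRNA", "mRNA", "lncRNA", "mRNA"),
                  c(4688, 16977, 1892, 42296)))
  flags <- stats::setNames(rep(FALSE, nrow(catalog)), catalog$transcript_id)
  flags[sprintf("dlnc%04d", 1:365)] <- TRUE
  flags[sprintf("dmrna%05d", 1:8894)] <- TRUE
  flags[sprintf("slnc%04d", 1:14)] <- TRUE
  flags[sprintf("smrna%05d", 1:74)] <- TRUE
  list(catalog = catalog, flags = flags)
}

# end-to-end system at the default conditions (error-free reads,
# 100k pairs per tissue), memoized for the acceptance checks
e2eSystem <- function() {
  memo("e2eSystem", {
    cfg <- simConfig(seed = 2026L, n_read_pairs_per_tissue = 100000L,
                     error_rate = 0)
    sim <- simulateParasiteSystem(cfg)
    ip <- buildSeedIndex(sim$genomes, "parasite")
    ih <- buildSeedIndex(sim$genomes, "host")
    sPar <- assignLibrary(sim$libraries$reads$parasite_stem, ip, ih)
    sHost <- assignLibrary(sim$libraries$reads$host_stem, ih, ip)
    sInt <- assignInterfaceLibrary(sim$libraries$reads$interface, ip, ih)
    cr <- countFragments(list(parasite_stem = sPar, interface = sInt,
                              host_stem = sHost), sim$genomes,
                         readLength = cfg@read_length)
    se <- computeFpkm(cr, sim$genomes)
    list(cfg = cfg, sim = sim,
         summaries = list(parasite_stem = sPar, interface = sInt,
                          host_stem = sHost),
         se = se, flags = callTranscriptMobility(se))
  })
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal SummarizedExperiment carrying an fpkm assay for statistics tests
makeFpkmSe <- function(fpkm, species, biotype,
                       mobile = matrix(0, nrow(fpkm), ncol(fpkm),
                                       dimnames = dimnames(fpkm))) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = fpkm, mobile_counts = mobile, fpkm = fpkm),
    rowData = S4Vectors::DataFrame(transcript_id = rownames(fpkm),
                                   species = species, biotype = biotype,
                                   row.names = rownames(fpkm)))
}
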