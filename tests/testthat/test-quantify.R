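test_that("FPKM follows the stated formula exactly", {
  # 10 fragments on a 1 kb transcript among 1e6 mapped fragments -> FPKM 10
  cr <- list(counts = matrix(c(10, 0), 2, 1,
                             dimnames = list(c("t1", "t2"), "parasite_stem")),
             mobile_counts = matrix(0, 2, 1,
                                    dimnames = list(c("t1", "t2"),
                                                    "parasite_stem")),
             intergenic = c(parasite_stem = 0),
             totals = c(parasite_stem = 1e6))
  chrom <- list(species = list("p"), chrom = list("chr1"),
                seq = list(strrep("ACGT", 2000)))
  gs <- manualGenomeSet(chrom, list(
    list(id = "t1", species = "p", chrom = "chr1", strand = "+",
         starts = 1L, ends = 1000L),
    list(id = "t2", species = "p", chrom = "chr1", strand = "+",
         starts = 2001L, ends = 2500L)))
  se <- computeFpkm(cr, gs)
  expect_equal(SummarizedExperiment::assay(se, "fpkm")["t1", 1], 10)
  expect_equal(SummarizedExperiment::assay(se, "fpkm")["t2", 1], 0)
  # scale invariance: doubling counts and totals leaves FPKM unchanged
  cr2 <- cr
  cr2$counts <- cr$counts * 2
  cr2$totals <- cr$totals * 2
  expect_equal(SummarizedExperiment::assay(computeFpkm(cr2, gs), "fpkm"),
               SummarizedExperiment::assay(se, "fpkm"))
  cr0 <- cr; cr0$totals <- c(parasite_stem = 0)
  expect_error(computeFpkm(cr0, gs), "zero mapped")
})

test_that("recomputation by an independent one-liner matches to 1e-9 relative", {
  set.seed(12)
  n <- 40
  lens <- sample(300:3000, n)
  counts <- matrix(rpois(n * 3, 50), n, 3,
                   dimnames = list(paste0("t", 1:n),
                                   c("parasite_stem", "interface", "host_stem")))
  chrom <- list(species = list("p"), chrom = list("chr1"),
                seq = list(randomDna(3000)))
  txs <- lapply(1:n, function(i) list(
    id = paste0("t", i), species = "p", chrom = "chr1", strand = "+",
    starts = 1L, ends = lens[i]))
  gs0 <- manualGenomeSet(chrom, txs)
  totals <- c(parasite_stem = 2e6, interface = 3e6, host_stem = 1.5e6)
  cr <- list(counts = counts, mobile_counts = counts * 0,
             intergenic = totals * 0, totals = totals)
  se <- computeFpkm(cr, gs0)
  expected <- sweep(sweep(counts * 1e9, 2, totals, "/"), 1,
                    txData(gs0)$spliced_length[
                      match(rownames(counts), txData(gs0)$transcript_id)], "/")
  expect_equal(SummarizedExperiment::assay(se, "fpkm"), expected,
               tolerance = 1e-9)
})

test_that("fragments are attributed to exon-overlapping transcripts with 1/n splits", {
  set.seed(14)
  chrom <- list(species = list("p"), chrom = list("chr1"),
                seq = list(randomDna(20000)))
  gs <- manualGenomeSet(chrom, list(
    list(id = "solo", species = "p", chrom = "chr1", strand = "+",
         starts = 1000L, ends = 2000L),
    list(id = "twinA", species = "p", chrom = "chr1", strand = "+",
         starts = 5000L, ends = 6000L),
    list(id = "twinB", species = "p", chrom = "chr1", strand = "+",
         starts = 5000L, ends = 6000L)))
  mkSummary <- function(labels) new("AssignmentSummary", tissue = "parasite_stem",
    counts = c(native = nrow(labels), mobile = 0, filtered = 0),
    conflicts = 0, labels = labels)
  lab <- S4Vectors::DataFrame(
    read_id = c("r1", "r2", "r3"),
    label = "native", conflict = FALSE,
    origin_species = "p",
    hit_ref = c("chr1", "chr1", "chr1"),
    hit_pos = c(1200L, 5100L, 9000L),
    hit_strand = "+", hit_is_transcript = FALSE, hit_mate = 1L)
  expect_message(
    cr <- countFragments(list(parasite_stem = mkSummary(lab)), gs,
                         readLength = 100L),
    "intergenic")
  expect_equal(cr$counts["solo", "parasite_stem"], 1)
  expect_equal(cr$counts["twinA", "parasite_stem"], 0.5)
  expect_equal(cr$counts["twinB", "parasite_stem"], 0.5)
  expect_equal(unname(cr$intergenic["parasite_stem"]), 1)
  expect_equal(unname(cr$totals["parasite_stem"]), 3)
})

test_that("error-free counts equal the truth-table tallies exactly", {
  cfg <- smallConfig(seed = 6L, unspliced_fraction = 0,
                     n_read_pairs_per_tissue = 1500L)
  sim <- simulateParasiteSystem(cfg)
  ip <- buildSeedIndex(sim$genomes, "parasite")
  ih <- buildSeedIndex(sim$genomes, "host")
  sPar <- assignLibrary(sim$libraries$reads$parasite_stem, ip, ih)
  sHost <- assignLibrary(sim$libraries$reads$host_stem, ih, ip)
  sInt <- assignInterfaceLibrary(sim$libraries$reads$interface, ip, ih)
  cr <- countFragments(list(parasite_stem = sPar, interface = sInt,
                            host_stem = sHost), sim$genomes,
                       readLength = cfg@read_length)
  for (tissue in c("parasite_stem", "interface", "host_stem")) {
    rd <- sim$libraries$reads[[tissue]]
    truth <- table(rd$truth_transcript_id)
    got <- cr$counts[, tissue]
    expect_equal(unname(got[names(truth)]), unname(as.numeric(truth)),
                 label = tissue)
    expect_equal(sum(got), nrow(rd), label = tissue)
    expect_equal(unname(cr$intergenic[tissue]), 0, label = tissue)
  }
})
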