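test_that("cotransfer joins mobility flags with referential integrity", {
  pairs <- data.frame(lncrna_id = c("l1", "l1", "l2"),
                      gene_id = c("g1", "g2", "g1"),
                      mode = c("cis", "trans", "cis"))
  flags <- c(l1 = TRUE, l2 = TRUE, g1 = TRUE, g2 = FALSE)
  res <- identifyCotransferPairs(pairs, flags)
  expect_identical(res$cotransfer, c(TRUE, FALSE, TRUE))
  cnt <- attr(res, "counts")
  expect_equal(unname(cnt$cis["pairs"]), 2)
  expect_equal(unname(cnt$cis["lncrnas"]), 2)
  # all-mobile: every pair co-transfers
  resAll <- identifyCotransferPairs(pairs, flags | TRUE)
  expect_true(all(resAll$cotransfer))
  expect_error(identifyCotransferPairs(pairs, flags[-1]),
               "referential-integrity")
})

test_that("co-transfer recovery matches a truth-table join on simulated data", {
  sys <- smallSystem()
  flags <- callTranscriptMobility(sys$se)
  td <- txData(sys$sim$genomes)
  pLnc <- td$transcript_id[td$species == "parasite" &
                             td$biotype == "lncRNA-truth"]
  pMrna <- td$transcript_id[td$species == "parasite" & td$biotype == "mRNA"]
  pairs <- predictCisTargets(sys$sim$genomes, pLnc, pMrna)
  res <- identifyCotransferPairs(pairs, flags)
  want <- flags[res$lncrna_id] & flags[res$gene_id]
  expect_identical(unname(res$cotransfer), unname(want))
})

test_that("family tallies equal a brute-force group-by", {
  pairs <- data.frame(lncrna_id = c("l1", "l2", "l1"),
                      gene_id = c("g1", "g2", "g3"))
  fam <- data.frame(gene_id = c("g1", "g2", "g3"),
                    family = c("MYB", "MYB", "WRKY"))
  out <- assignTfFamilies(pairs, fam)
  myb <- out[out$family == "MYB", ]
  expect_equal(myb$n_genes, 2)
  expect_equal(myb$n_lncrnas, 2)
  expect_equal(out[out$family == "WRKY", ]$n_lncrnas, 1)
  expect_equal(nrow(assignTfFamilies(pairs[0, ], fam)), 0)
  # unassigned bucket
  out2 <- assignTfFamilies(pairs, fam[1, , drop = FALSE])
  expect_true("unassigned" %in% out2$family)
  # random maps vs independent tally
  set.seed(91)
  rp <- data.frame(lncrna_id = sample(paste0("l", 1:20), 200, replace = TRUE),
                   gene_id = sample(paste0("g", 1:50), 200, replace = TRUE))
  rf <- data.frame(gene_id = paste0("g", 1:50),
                   family = sample(LETTERS[1:5], 50, replace = TRUE))
  out3 <- assignTfFamilies(rp, rf)
  for (i in seq_len(nrow(out3))) {
    genes <- rf$gene_id[rf$family == out3$family[i]]
    sub <- rp[rp$gene_id %in% genes, ]
    expect_equal(out3$n_genes[i], length(unique(sub$gene_id)))
    expect_equal(out3$n_lncrnas[i], length(unique(sub$lncrna_id)))
  }
})

test_that("network export writes SIF and round-trips the edge table", {
  pairs <- data.frame(lncrna_id = "lnc1", gene_id = "geneA", mode = "cis",
                      distance_bp = 5000L)
  dir <- file.path(tempdir(), "net")
  paths <- exportNetwork(pairs, dir,
                         familyMap = data.frame(gene_id = "geneA",
                                                family = "MYB"))
  expect_identical(readLines(paths[["sif"]]), "lnc1 targets geneA")
  back <- readNetworkEdges(paths[["edges"]])
  expect_equal(back$lncrna_id, pairs$lncrna_id)
  expect_equal(back$distance_bp, pairs$distance_bp)
  nodes <- utils::read.table(paths[["nodes"]], sep = "\t", header = TRUE)
  expect_identical(nodes$role[nodes$node == "geneA"], "TF")
  expect_identical(nodes$role[nodes$node == "lnc1"], "lncRNA")
  expect_error(exportNetwork(data.frame(lncrna_id = "x", gene_id = "x",
                                        mode = "cis"), dir), "self-edges")
  unlink(dir, recursive = TRUE)
})

test_that("term-filtered subnetworks equal a brute-force filter", {
  set.seed(92)
  pairs <- data.frame(lncrna_id = sample(paste0("l", 1:10), 100, replace = TRUE),
                      gene_id = sample(paste0("g", 1:30), 100, replace = TRUE),
                      mode = "trans")
  termMap <- data.frame(term_id = rep(c("T1", "T2"), c(15, 15)),
                        gene_id = sample(paste0("g", 1:30), 30))
  sub <- filterNetworkByTerm(pairs, termMap, "T1")
  want <- pairs[pairs$gene_id %in% termMap$gene_id[termMap$term_id == "T1"], ]
  expect_identical(sub, want)
})
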