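# reference layout on a 100 kb toy chromosome (single species "p"):
# geneA: + strand, exons [10000,10500], [11000,11600]
# geneB: - strand, exons [30000,30400], [31000,31500]
classCodeFixture <- function() {
  set.seed(31)
  chrom <- list(species = list("p"), chrom = list("chr1"),
                seq = list(randomDna(100000)))
  refs <- list(
    list(id = "geneA", species = "p", chrom = "chr1", strand = "+",
         starts = c(10000L, 11000L), ends = c(10500L, 11600L)),
    list(id = "geneB", species = "p", chrom = "chr1", strand = "-",
         starts = c(30000L, 31000L), ends = c(30400L, 31500L)))
  cands <- list(
    list(id = "c_u", species = "p", chrom = "chr1", strand = "+",
         starts = c(60000L, 61000L), ends = c(60300L, 61400L)),
    list(id = "c_eq", species = "p", chrom = "chr1", strand = "+",
         starts = c(10000L, 11000L), ends = c(10500L, 11600L)),
    list(id = "c_i", species = "p", chrom = "chr1", strand = "+",
         starts = 10600L, ends = 10900L),
    list(id = "c_x", species = "p", chrom = "chr1", strand = "+",
         starts = 30100L, ends = 30600L),
    list(id = "c_o", species = "p", chrom = "chr1", strand = "+",
         starts = c(10400L, 11200L), ends = c(10600L, 11300L)),
    list(id = "c_e", species = "p", chrom = "chr1", strand = "+",
         starts = 10300L, ends = 10800L),
    list(id = "c_other", species = "p", chrom = "chr1", strand = "+",
         starts = c(10600L, 11700L), ends = c(10900L, 11900L)))
  manualGenomeSet(chrom, c(refs, cands))
}

test_that("hand-placed candidates receive their definitional class codes", {
  gs <- classCodeFixture()
  ex <- transcriptExons(gs)
  codes <- assignClassCode(ex[c("c_u", "c_eq", "c_i", "c_x", "c_o",
                                "c_e", "c_other")],
                           ex[c("geneA", "geneB")])
  expect_identical(unname(codes),
                   c("u", "=", "i", "x", "o", "e", "other"))
})

test_that("a candidate on an unknown chromosome raises a coordinate error", {
  gs <- classCodeFixture()
  ex <- transcriptExons(gs)
  expect_error(assignClassCode(ex["c_u"], ex["geneA"], chromNames = "chrX"),
               "unknown chromosome")
})

test_that("class codes equal the interval-logic oracle on random candidates", {
  set.seed(77)
  chromLen <- 200000L
  nRefs <- 20L
  refs <- list()
  pos <- 5000L
  for (i in seq_len(nRefs)) {
    k <- sample(1:4, 1)
    exLens <- sample(100:400, k, replace = TRUE)
    inLens <- if (k > 1) sample(100:500, k - 1, replace = TRUE) else integer()
    starts <- integer(k); ends <- integer(k)
    p <- pos
    for (j in seq_len(k)) {
      starts[j] <- p; ends[j] <- p + exLens[j] - 1L
      p <- ends[j] + (if (j < k) inLens[j] else 0L) + 1L
    }
    refs[[i]] <- list(id = paste0("ref", i), species = "p", chrom = "chr1",
                      strand = sample(c("+", "-"), 1),
                      starts = starts, ends = ends)
    pos <- p + sample(500:3000, 1)
  }
  cands <- list()
  for (i in seq_len(500)) {
    k <- sample(1:3, 1)
    s0 <- sample(chromLen - 5000L, 1)
    exLens <- sample(80:400, k, replace = TRUE)
    inLens <- if (k > 1) sample(50:600, k - 1, replace = TRUE) else integer()
    starts <- integer(k); ends <- integer(k)
    p <- s0
    for (j in seq_len(k)) {
      starts[j] <- p; ends[j] <- p + exLens[j] - 1L
      p <- ends[j] + (if (j < k) inLens[j] else 0L) + 1L
    }
    cands[[i]] <- list(id = paste0("c", i), species = "p", chrom = "chr1",
                       strand = sample(c("+", "-"), 1),
                       starts = starts, ends = ends)
  }
  chrom <- list(species = list("p"), chrom = list("chr1"),
                seq = list(randomDna(1000)))  # sequence content irrelevant here
  # build GRangesLists directly (coordinates may exceed the toy sequence)
  mk <- function(lst) {
    GenomicRanges::GRangesList(lapply(stats::setNames(lst, vapply(lst, `[[`, "", "id")),
      function(t) GenomicRanges::GRanges(
        t$chrom, IRanges::IRanges(t$starts, t$ends), strand = t$strand)))
  }
  codes <- assignClassCode(mk(cands), mk(refs))
  for (i in seq_along(cands)) {
    expected <- oracleClassCode(cands[[i]]$starts, cands[[i]]$ends,
                                cands[[i]]$strand, refs)
    expect_identical(unname(codes[i]), expected,
                     label = paste("candidate", i))
  }
})

test_that("the positional type map is total over the filtered codes", {
  expect_identical(classifyLncrnaType(c("u", "x", "i", "o", "e")),
                   c("lincRNA", "antisense", "intronic", "sense", "sense"))
  expect_error(classifyLncrnaType("="), "classification error")
  expect_error(classifyLncrnaType("other"), "classification error")
})
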