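test_that("the rule table never labels a native-matching read mobile", {
  set.seed(1)
  for (i in 1:200) {
    mn <- sample(c(TRUE, FALSE), 1)
    mf <- sample(c(TRUE, FALSE), 1)
    lab <- lncMobility:::.labelFromMatches(mn, mf)
    if (mn) expect_identical(lab, "native")
    else if (mf) expect_identical(lab, "mobile")
    else expect_identical(lab, "filtered")
  }
})

test_that("single-read assignment follows the dual-genome rule", {
  sys <- smallSystem()
  gs <- sys$sim$genomes
  gp <- as.character(genomeSeq(gs, "parasite")[[1]])
  gh <- as.character(genomeSeq(gs, "host")[[1]])
  readP <- substr(gp, 1001, 1100)   # parasite-only sequence
  readH <- substr(gh, 1001, 1100)
  junk <- strrep("N", 100)
  labs <- assignRead(c(readP, readH, junk), sys$ip, sys$ih)
  expect_identical(labs, c("native", "mobile", "filtered"))
})

test_that("error-free truth-mobile fragments are all labeled mobile", {
  sys <- smallSystem()
  hs <- sys$sim$libraries$reads$host_stem
  lab <- readLabels(sys$summaries$host_stem)
  truthForeign <- hs$truth_species == "parasite"
  expect_identical(unname(lab$label == "mobile"), unname(truthForeign))
  expect_true(all(lab$origin_species[truthForeign] == "parasite"))
})

test_that("labels partition every library and conserve totals", {
  sys <- smallSystem()
  for (tissue in c("parasite_stem", "host_stem")) {
    s <- sys$summaries[[tissue]]
    cnt <- assignmentCounts(s)
    expect_equal(sum(cnt), nrow(sys$sim$libraries$reads[[tissue]]))
    expect_equal(sum(table(readLabels(s)$label)), sum(cnt))
  }
  ic <- sys$summaries$interface
  expect_equal(sum(ic$counts), nrow(sys$sim$libraries$reads$interface))
})

test_that("zero mobility and zero errors give exactly zero foreign reads", {
  cfg <- smallConfig(seed = 5L, mobile_fraction_parasite_to_host = 0,
                     mobile_fraction_host_to_parasite = 0,
                     n_read_pairs_per_tissue = 1500L)
  sim <- simulateParasiteSystem(cfg)
  ip <- buildSeedIndex(sim$genomes, "parasite")
  ih <- buildSeedIndex(sim$genomes, "host")
  sPar <- assignLibrary(sim$libraries$reads$parasite_stem, ip, ih)
  sHost <- assignLibrary(sim$libraries$reads$host_stem, ih, ip)
  expect_identical(foreignReadProportion(sPar), 0)
  expect_identical(foreignReadProportion(sHost), 0)
  expect_equal(assignmentCounts(sPar)[["filtered"]], 0)
})

test_that("an empty library reports undefined proportion, never zero", {
  sys <- smallSystem()
  empty <- sys$sim$libraries$reads$host_stem[0, ]
  s <- assignLibrary(empty, sys$ih, sys$ip, tissue = "host_stem")
  expect_equal(unname(assignmentCounts(s)), c(0, 0, 0))
  expect_true(is.na(foreignReadProportion(s)))
})

test_that("estimated foreign proportions are unbiased across seeded replicates", {
  sys <- smallSystem()
  gs <- sys$sim$genomes
  for (f in c(0.001, 0.005, 0.015)) {
    mobileTotal <- 0
    nTotal <- 0
    for (rep in 1:6) {
      cfg <- smallConfig(seed = 100L + rep,
                         n_read_pairs_per_tissue = 5000L,
                         mobile_fraction_parasite_to_host = f)
      expr <- simulateExpression(gs, cfg)
      libs <- simulateLibraries(gs, expr, cfg)
      s <- assignLibrary(libs$reads$host_stem, sys$ih, sys$ip)
      mobileTotal <- mobileTotal + assignmentCounts(s)[["mobile"]]
      nTotal <- nTotal + sum(assignmentCounts(s)[c("native", "mobile")])
    }
    sigma <- sqrt(f * (1 - f) / nTotal)
    expect_lt(abs(mobileTotal / nTotal - f), 3 * sigma, label = paste("f =", f))
  }
})

test_that("interface fragments are labeled per species with no mobile class", {
  sys <- smallSystem()
  ic <- sys$summaries$interface
  rd <- sys$sim$libraries$reads$interface
  expect_false("mobile" %in% ic$labels$label)
  solid <- ic$labels$label %in% c("parasite", "host")
  expect_identical(unname(ic$labels$label[solid]),
                   unname(rd$truth_species[solid]))
  # the species mixture reflects the configured interface_mix
  pFrac <- mean(rd$truth_species == "parasite")
  sigma <- sqrt(0.5 * 0.5 / nrow(rd))
  expect_lt(abs(pFrac - sys$cfg@interface_mix), 3 * sigma)
})
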