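# fpkm values such that log10(fpkm + 1e-3) equals chosen x exactly
fpkmForLog <- function(x) 10^x - 1e-3

test_that("the interface regression recovers exact lines", {
  x <- c(0.2, 0.7, 1.1, 1.6, 2.3)
  se <- makeFpkmSe(
    cbind(parasite_stem = fpkmForLog(x * 0 + 1), interface = fpkmForLog(x),
          host_stem = fpkmForLog(2 * x + 1)) |>
      `rownames<-`(paste0("t", 1:5)),
    species = rep("parasite", 5), biotype = rep("lncRNA", 5))
  flags <- stats::setNames(rep(TRUE, 5), paste0("t", 1:5))
  fit <- interfaceCorrelation(se, flags, species = "parasite")
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$n, 5)
  # three specified points (1,1),(2,3),(3,5)
  se3 <- makeFpkmSe(
    cbind(parasite_stem = fpkmForLog(c(1, 1, 1)),
          interface = fpkmForLog(c(1, 2, 3)),
          host_stem = fpkmForLog(c(1, 3, 5))) |>
      `rownames<-`(paste0("u", 1:3)),
    species = rep("parasite", 3), biotype = rep("lncRNA", 3))
  fit3 <- interfaceCorrelation(se3, stats::setNames(rep(TRUE, 3),
                                                    paste0("u", 1:3)))
  expect_equal(fit3$slope, 2, tolerance = 1e-9)
  expect_equal(fit3$intercept, -1, tolerance = 1e-9)
  expect_equal(fit3$r, 1, tolerance = 1e-9)
})

test_that("OLS matches the closed form on random data and refuses < 3 points", {
  set.seed(19)
  n <- 500
  x <- rnorm(n); y <- 1.3 * x + rnorm(n)
  # keep every pseudo-FPKM positive so the oracle sees the same points
  keep <- x > -2.5 & y > -2.5
  x <- x[keep]; y <- y[keep]; n <- length(x)
  se <- makeFpkmSe(
    cbind(parasite_stem = fpkmForLog(x * 0), interface = fpkmForLog(x),
          host_stem = fpkmForLog(y)) |>
      `rownames<-`(paste0("t", 1:n)),
    species = rep("parasite", n), biotype = rep("lncRNA", n))
  flags <- stats::setNames(rep(TRUE, n), paste0("t", 1:n))
  fit <- interfaceCorrelation(se, flags)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit$slope, slope, tolerance = 1e-9)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-9)
  expect_equal(fit$r, r, tolerance = 1e-9)
  flags2 <- flags; flags2[3:n] <- FALSE
  expect_error(interfaceCorrelation(se, flags2), "insufficient")
})

test_that("z-scoring centres and scales rows, flagging constant ones", {
  set.seed(20)
  m <- matrix(rlnorm(150), 50, 3,
              dimnames = list(paste0("t", 1:50),
                              c("parasite_stem", "interface", "host_stem")))
  m[1, ] <- 1  # constant row
  se <- makeFpkmSe(m, species = rep("parasite", 50),
                   biotype = rep("lncRNA", 50))
  z <- zscoreMatrix(se)
  expect_equal(unname(z[1, ]), c(0, 0, 0))
  expect_true(attr(z, "constant")[["t1"]])
  expect_lt(max(abs(rowMeans(z[-1, ]))), 1e-9)
  expect_lt(max(abs(apply(z[-1, ], 1, stats::sd) - 1)), 1e-9)
  # base-10 variant changes values but not the z-score identity
  z10 <- zscoreMatrix(se, base = 10)
  expect_lt(max(abs(rowMeans(z10[-1, ]))), 1e-9)
  expect_error(zscoreMatrix(se, tissues = "interface"), "at least 2")
})

test_that("abundance summaries report medians and a directional test", {
  se <- makeFpkmSe(
    cbind(parasite_stem = c(1, 1), interface = c(7, 3), host_stem = c(1, 1)) |>
      `rownames<-`(c("m1", "n1")),
    species = rep("parasite", 2), biotype = rep("lncRNA", 2))
  flags <- c(m1 = TRUE, n1 = FALSE)
  s <- abundanceMobilitySummary(se, flags)
  expect_equal(s$mobile_median, log2(7 + 1))
  expect_equal(s$nonmobile_median, log2(3 + 1))
  expect_equal(s$n_mobile, 1)
  # empty set: no test
  sEmpty <- abundanceMobilitySummary(se, c(m1 = FALSE, n1 = FALSE))
  expect_true(is.na(sEmpty$p_greater))
})

test_that("the Mann-Whitney comparison is calibrated under the null", {
  set.seed(23)
  nrep <- 100
  rejected <- 0
  for (i in seq_len(nrep)) {
    fpkm <- matrix(rlnorm(60 * 3, 1, 1), 60, 3,
                   dimnames = list(paste0("t", 1:60),
                                   c("parasite_stem", "interface", "host_stem")))
    se <- makeFpkmSe(fpkm, species = rep("parasite", 60),
                     biotype = rep("lncRNA", 60))
    flags <- stats::setNames(seq_len(60) %in% sample(60, 30), paste0("t", 1:60))
    s <- abundanceMobilitySummary(se, flags)
    if (s$p_greater < 0.05) rejected <- rejected + 1
  }
  rate <- rejected / nrep
  sigma <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rate - 0.05), 3 * sigma)
})
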