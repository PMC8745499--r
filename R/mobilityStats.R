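#' @include mobility.R
#' @importFrom stats median quantile wilcox.test lm coef cor rlnorm rbinom
#'   rgamma rgeom runif rnorm
NULL

#' Interface-tissue abundance of mobile versus non-mobile transcripts
#'
#' Compares log2(FPKM + 1) in the interface tissue between mobile and
#' non-mobile transcripts, per species and biotype, with a one-sided
#' Mann-Whitney U test (alternative: mobile abundance is greater). A set with
#' no members yields undefined statistics and no test.
#'
#' @param se expression matrix from [computeFpkm()] with an `interface`
#'   column.
#' @param mobileFlags named logical vector from [callTranscriptMobility()].
#' @param species restrict to one species of origin (default: both,
#'   separately).
#' @return data.frame with one row per (species, biotype): group sizes,
#'   medians and quartiles of log2(FPKM+1), and the one-sided p-value.
#' @export
abundanceMobilitySummary <- function(se, mobileFlags, species = NULL) {
  stopifnot("interface" %in% colnames(se))
  rd <- rowData(se)
  bt <- rd$biotype
  bt[bt == "lncRNA-truth"] <- "lncRNA"
  lf <- log2(assay(se, "fpkm")[, "interface"] + 1)
  flags <- mobileFlags[rownames(se)]
  specs <- if (is.null(species)) unique(rd$species) else species
  rows <- list()
  for (sp in specs) for (b in unique(bt)) {
    in_set <- rd$species == sp & bt == b
    mob <- lf[in_set & flags]
    non <- lf[in_set & !flags]
    q <- function(v) if (length(v)) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
                     else rep(NA_real_, 3)
    p <- if (length(mob) && length(non))
      suppressWarnings(wilcox.test(mob, non, alternative = "greater")$p.value)
    else NA_real_
    qm <- q(mob); qn <- q(non)
    rows[[paste(sp, b)]] <- data.frame(
      species = sp, biotype = b, n_mobile = length(mob),
      n_nonmobile = length(non),
      mobile_q1 = qm[1], mobile_median = qm[2], mobile_q3 = qm[3],
      nonmobile_q1 = qn[1], nonmobile_median = qn[2], nonmobile_q3 = qn[3],
      p_greater = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of foreign-stem on interface expression of mobile transcripts
#'
#' Ordinary least squares of log10(FPKM + eps) in the foreign stem tissue on
#' log10(FPKM + eps) in the interface, over mobile transcripts of one
#' species. Requires at least 3 mobile transcripts with positive FPKM in
#' both tissues.
#'
#' @param se expression matrix from [computeFpkm()].
#' @param mobileFlags named logical vector.
#' @param species species of origin of the mobile transcripts (default
#'   `"parasite"`, whose foreign stem is `host_stem`).
#' @param eps pseudo-FPKM added before taking logs (default `1e-3`).
#' @return list with `slope`, `intercept`, `r`, `n`.
#' @export
interfaceCorrelation <- function(se, mobileFlags, species = "parasite",
                                 eps = 1e-3) {
  foreignTissue <- if (species == "parasite") "host_stem" else "parasite_stem"
  fpkm <- assay(se, "fpkm")
  sel <- rowData(se)$species == species & mobileFlags[rownames(se)] &
    fpkm[, foreignTissue] > 0 & fpkm[, "interface"] > 0
  if (sum(sel) < 3)
    stop("insufficient data: need >= 3 mobile transcripts with positive FPKM ",
         "in both tissues (have ", sum(sel), ")")
  x <- log10(fpkm[sel, "interface"] + eps)
  y <- log10(fpkm[sel, foreignTissue] + eps)
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(x, y), n = sum(sel))
}

#' Row z-scored expression matrix for heatmaps
#'
#' Per transcript row, z = (log_b(FPKM + eps) - row mean) / row SD over the
#' selected tissues; base 2 or 10. Rows with zero spread are emitted as
#' all-zero and flagged in the `constant` attribute.
#'
#' @param se expression matrix from [computeFpkm()].
#' @param ids transcript ids (rows) to include, default all.
#' @param tissues tissue columns, default all (>= 2 required).
#' @param base log base, 2 or 10.
#' @param eps pseudo-FPKM, default `1e-3`.
#' @return numeric matrix with attribute `constant` (logical per row).
#' @export
zscoreMatrix <- function(se, ids = rownames(se), tissues = colnames(se),
                         base = 2, eps = 1e-3) {
  if (length(tissues) < 2) stop("need at least 2 tissues to z-score")
  m <- log(assay(se, "fpkm")[ids, tissues, drop = FALSE] + eps, base = base)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  constant <- sd == 0 | is.na(sd)
  z <- (m - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  attr(z, "constant") <- stats::setNames(constant, ids)
  z
}
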