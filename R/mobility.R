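#' @include quantify.R
NULL

# half-up decimal rounding so printed table arithmetic is bit-reproducible
.roundHalfUp <- function(x, digits) {
  out <- floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
  out[is.na(x)] <- NA_real_
  out
}

# printed precision: one decimal at >= 1%, two decimals below 1%
.formatPercent <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) >= 1, .roundHalfUp(x, 1), .roundHalfUp(x, 2)))
}

#' Call transcript-level mobility
#'
#' A transcript of species A is mobile when at least `min_mobile_fragments`
#' mobile-labeled fragments are attributed to it in species B's pure stem
#' tissue. Detection in the interface tissue never confers mobility (the
#' interface contains both species' RNA by construction).
#'
#' @param se expression matrix from [computeFpkm()] (needs the
#'   `mobile_counts` assay and stem-tissue columns).
#' @param min_mobile_fragments detection threshold, default 1 fragment.
#' @return named logical vector over transcripts.
#' @export
callTranscriptMobility <- function(se, min_mobile_fragments = 1) {
  mob <- assay(se, "mobile_counts")
  sp <- rowData(se)$species
  out <- stats::setNames(rep(FALSE, nrow(se)), rownames(se))
  if ("host_stem" %in% colnames(mob))
    out[sp == "parasite"] <- mob[sp == "parasite", "host_stem"] >= min_mobile_fragments
  if ("parasite_stem" %in% colnames(mob))
    out[sp == "host"] <- mob[sp == "host", "parasite_stem"] >= min_mobile_fragments
  out
}

#' Build the mobility tally table
#'
#' Counts mobile and non-mobile transcripts per (species, biotype) cell.
#' Percentages are recomputed on demand by [mobilityPercentages()] and never
#' stored.
#'
#' @param mobileFlags named logical vector (transcript ids).
#' @param catalog data.frame or DataFrame with `transcript_id`, `species` and
#'   `biotype` columns (a [txData()] table works; `lncRNA-truth` is reported
#'   as `lncRNA`).
#' @return a [MobilityTable].
#' @export
buildMobilityTable <- function(mobileFlags, catalog) {
  catalog <- as.data.frame(catalog)
  if (!nrow(catalog)) stop("empty catalog: nothing to tally")
  bt <- catalog$biotype
  bt[bt == "lncRNA-truth"] <- "lncRNA"
  flags <- mobileFlags[match(catalog$transcript_id, names(mobileFlags))]
  flags[is.na(flags)] <- FALSE
  cells <- unique(data.frame(species = catalog$species, biotype = bt,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$species, cells$biotype), ]
  m <- sapply(seq_len(nrow(cells)), function(i) {
    in_cell <- catalog$species == cells$species[i] & bt == cells$biotype[i]
    c(mobile = sum(flags[in_cell]),
      nonmobile = sum(in_cell) - sum(flags[in_cell]),
      total = sum(in_cell))
  })
  m <- matrix(m, nrow = 3,
              dimnames = list(c("mobile", "nonmobile", "total"),
                              paste(cells$species, cells$biotype, sep = ":")))
  new("MobilityTable", counts = m, species = cells$species,
      biotype = cells$biotype)
}

#' Derived percentages of a mobility table
#'
#' Per-cell mobile percentage (100 x mobile/total, printed precision: one
#' decimal at or above 1%, two below) and, per biotype, the cross-species
#' ratio 100 x host-mobile / parasite-mobile (two decimals). All values are
#' recomputed from the counts.
#'
#' @param table a [MobilityTable].
#' @param hostLabel,parasiteLabel species labels used for the cross-species
#'   ratios.
#' @return list with `mobile_pct` (data.frame per cell) and `cross_ratio`
#'   (named numeric per biotype).
#' @export
mobilityPercentages <- function(table, hostLabel = "host",
                                parasiteLabel = "parasite") {
  m <- mobilityCounts(table)
  pct <- ifelse(m["total", ] > 0, 100 * m["mobile", ] / m["total", ], NA_real_)
  mobile_pct <- data.frame(species = table@species, biotype = table@biotype,
                           mobile = m["mobile", ], total = m["total", ],
                           mobile_pct = .formatPercent(pct),
                           row.names = NULL)
  ratios <- c()
  for (bt in unique(table@biotype)) {
    hCol <- which(table@species == hostLabel & table@biotype == bt)
    pCol <- which(table@species == parasiteLabel & table@biotype == bt)
    if (length(hCol) == 1 && length(pCol) == 1 && m["mobile", pCol] > 0)
      ratios[bt] <- .roundHalfUp(100 * m["mobile", hCol] / m["mobile", pCol], 2)
    else ratios[bt] <- NA_real_
  }
  list(mobile_pct = mobile_pct, cross_ratio = ratios)
}
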