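#' @include genomeSim.R
NULL

#' Simulate per-transcript abundances and the mobile pool
#'
#' Draws a log-normal relative abundance for every transcript in every tissue
#' (one base abundance per transcript, shared across tissues) and samples the
#' abundance-biased mobile pool: each transcript's propensity to move is
#' proportional to abundance^`abundance_mobility_bias`, scaled so that the
#' expected pool size is `mobile_pool_fraction` of the species' catalog. When
#' a direction's mobile fraction is 0 its pool is empty. Foreign reads are
#' later drawn from the pool with abundance weights so that the expected
#' foreign-read fraction per stem tissue equals the configured
#' `mobile_fraction_*`.
#'
#' @param genomes a [GenomeSet].
#' @param config the [SimConfig] used to generate it.
#' @return a list with `abundance` (named numeric, relative weights),
#'   `mobile_pool` (named list of transcript ids per species) and
#'   `propensity` (named numeric in `[0,1]`).
#' @export
simulateExpression <- function(genomes, config) {
  validObject(genomes)
  set.seed(.stageSeed(config, "expression"))
  td <- txData(genomes)
  n <- nrow(td)
  abundance <- stats::setNames(rlnorm(n, meanlog = 0, sdlog = 1.2),
                               td$transcript_id)
  pool <- list(parasite = character(), host = character())
  propensity <- stats::setNames(numeric(n), td$transcript_id)
  for (sp in speciesNames(genomes)) {
    frac <- if (sp == "parasite") config@mobile_fraction_parasite_to_host
            else config@mobile_fraction_host_to_parasite
    ids <- td$transcript_id[td$species == sp]
    if (frac == 0 || !length(ids)) next
    w <- abundance[ids]^config@abundance_mobility_bias
    p <- w / mean(w) * config@mobile_pool_fraction
    p <- pmin(p, 1)
    propensity[ids] <- p
    sel <- ids[runif(length(ids)) < p]
    # a direction with a positive mobile fraction needs a non-empty pool
    if (!length(sel)) sel <- ids[which.max(p)]
    pool[[sp]] <- sel
  }
  list(abundance = abundance, mobile_pool = pool, propensity = propensity)
}
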