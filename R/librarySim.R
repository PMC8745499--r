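#' @include expressionSim.R
NULL

.TISSUES <- c("parasite_stem", "interface", "host_stem")

# pre-RNA (transcript orientation) of a set of transcripts, from the genome
.preRnaSeqs <- function(genomes, ids) {
  td <- txData(genomes)
  td <- td[match(ids, td$transcript_id), , drop = FALSE]
  out <- character(length(ids))
  for (sp in unique(td$species)) {
    sel <- which(td$species == sp)
    ex <- transcriptExons(genomes)[ids[sel]]
    spans <- unlist(range(ex))
    g <- genomeSeq(genomes, sp)
    seqs <- Biostrings::subseq(rep(g[td$chrom[sel]], 1L),
                               start = GenomicRanges::start(spans),
                               end = GenomicRanges::end(spans))
    minus <- td$strand[sel] == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    out[sel] <- as.character(seqs)
  }
  names(out) <- ids
  out
}

.addErrors <- function(reads, rate) {
  if (rate == 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  nerr <- rbinom(length(reads), L, rate)
  for (i in which(nerr > 0L)) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample.int(L[i], nerr[i])
    s[at] <- vapply(s[at], function(b) sample(setdiff(.BASES, b), 1L), "")
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate tissue read libraries with recorded ground truth
#'
#' Draws paired-end reads for the three tissue libraries of a parasitic
#' system: pure parasite stem, the haustorial interface, and pure host stem.
#' Native reads come from the native species' transcripts (mature sequence,
#' or the unspliced pre-RNA with probability `unspliced_fraction`); foreign
#' (mobile) reads appear only in the two pure stem tissues, are drawn from
#' the foreign species' mobile pool with abundance weights, and always come
#' from the fully spliced mature sequence. The interface mixes both species'
#' native transcripts. Substitution errors are applied at `error_rate`.
#' Read starts are uniform over the template; templates shorter than the read
#' length are skipped with a warning and counted.
#'
#' @param genomes a [GenomeSet].
#' @param abundances result of [simulateExpression()].
#' @param config the [SimConfig].
#' @return a list with `reads` (per-tissue [S4Vectors::DataFrame] of
#'   `read_id`, `tissue`, `truth_species`, `truth_transcript_id`,
#'   `truth_spliced`, `mate1`, `mate2`) and `skipped` (named skip counts).
#' @export
simulateLibraries <- function(genomes, abundances, config) {
  set.seed(.stageSeed(config, "libraries"))
  td <- txData(genomes)
  ab <- abundances$abundance
  pool <- abundances$mobile_pool
  L <- config@read_length
  npairs <- config@n_read_pairs_per_tissue
  pre <- .preRnaSeqs(genomes, td$transcript_id)
  spl <- splicedSeqs(genomes)
  out <- list()
  skipped <- stats::setNames(numeric(length(.TISSUES)), .TISSUES)
  for (tissue in .TISSUES) {
    if (tissue == "interface") {
      fromPar <- runif(npairs) < config@interface_mix
      sp <- ifelse(fromPar, "parasite", "host")
      isForeign <- rep(FALSE, npairs)
    } else {
      nativeSp <- if (tissue == "parasite_stem") "parasite" else "host"
      foreignSp <- setdiff(c("parasite", "host"), nativeSp)
      f <- if (tissue == "host_stem") config@mobile_fraction_parasite_to_host
           else config@mobile_fraction_host_to_parasite
      isForeign <- runif(npairs) < f & length(pool[[foreignSp]]) > 0
      sp <- ifelse(isForeign, foreignSp, nativeSp)
    }
    txid <- character(npairs)
    for (s in unique(sp)) {
      selF <- which(sp == s & isForeign)
      selN <- which(sp == s & !isForeign)
      if (length(selF)) {
        ids <- pool[[s]]
        txid[selF] <- if (length(ids) == 1L) ids else
          sample(ids, length(selF), replace = TRUE, prob = ab[ids])
      }
      if (length(selN)) {
        ids <- td$transcript_id[td$species == s]
        if (!length(ids))
          stop("species ", s, " has no transcripts to draw native reads from")
        txid[selN] <- if (length(ids) == 1L) ids else
          sample(ids, length(selN), replace = TRUE, prob = ab[ids])
      }
    }
    unspliced <- !isForeign & runif(npairs) < config@unspliced_fraction
    tpl <- ifelse(unspliced, pre[txid], spl[txid])
    ok <- nchar(tpl) >= L
    if (any(!ok)) {
      skipped[tissue] <- sum(!ok)
      warning(sum(!ok), " read pairs skipped in ", tissue,
              ": template shorter than read length")
    }
    idx <- which(ok)
    n <- length(idx)
    tlen <- nchar(tpl[idx])
    s1 <- 1L + floor(runif(n) * (tlen - L + 1L))
    s2 <- 1L + floor(runif(n) * (tlen - L + 1L))
    mate1 <- .addErrors(substring(tpl[idx], s1, s1 + L - 1L), config@error_rate)
    mate2 <- .addErrors(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(substring(tpl[idx], s2, s2 + L - 1L)))),
      config@error_rate)
    out[[tissue]] <- DataFrame(
      read_id = sprintf("%s_%07d", tissue, seq_len(n)),
      tissue = tissue,
      truth_species = sp[idx],
      truth_transcript_id = txid[idx],
      truth_spliced = !unspliced[idx],
      mate1 = mate1, mate2 = mate2)
  }
  list(reads = out, skipped = skipped)
}

#' Run the full simulation in one call
#'
#' Convenience wrapper chaining [generateGenomePair()],
#' [simulateExpression()] and [simulateLibraries()].
#'
#' @param config a [SimConfig].
#' @return list with `genomes`, `expression`, `libraries`.
#' @export
simulateParasiteSystem <- function(config) {
  genomes <- generateGenomePair(config)
  expr <- simulateExpression(genomes, config)
  libs <- simulateLibraries(genomes, expr, config)
  list(genomes = genomes, expression = expr, libraries = libs)
}

#' Realized mobile transcript set of a simulation
#'
#' Transcripts of each species with at least one foreign-origin read in the
#' other species' stem library — the operational ground truth for
#' transcript-level mobility recovery.
#'
#' @param libraries result of [simulateLibraries()].
#' @return named list of transcript id vectors per species of origin.
#' @export
truthMobileSet <- function(libraries) {
  rd <- libraries$reads
  list(
    parasite = sort(unique(rd$host_stem$truth_transcript_id[
      rd$host_stem$truth_species == "parasite"])),
    host = sort(unique(rd$parasite_stem$truth_transcript_id[
      rd$parasite_stem$truth_species == "host"]))
  )
}
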