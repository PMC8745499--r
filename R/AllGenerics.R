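#' @include AllClasses.R
NULL

#' Accessors for lncMobility classes
#'
#' `genomeSeq()` returns one species' genome sequences, `speciesNames()` the
#' species labels, `txData()` the transcript catalog, `transcriptExons()` the
#' per-transcript exon ranges, `splicedSeqs()` the mature sequences,
#' `readLabels()` the per-fragment label table, `assignmentCounts()` the
#' native/mobile/filtered tallies, `conflictCount()` the mate-conflict tally,
#' and `mobilityCounts()` the tally matrix of a [MobilityTable].
#'
#' @param x a `GenomeSet`, `AssignmentSummary` or `MobilityTable`.
#' @param species species label (e.g. `"parasite"`).
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x, species) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))

#' @rdname accessors
#' @export
setGeneric("transcriptExons", function(x) standardGeneric("transcriptExons"))

#' @rdname accessors
#' @export
setGeneric("splicedSeqs", function(x, species) standardGeneric("splicedSeqs"))

#' @rdname accessors
#' @export
setGeneric("readLabels", function(x) standardGeneric("readLabels"))

#' @rdname accessors
#' @export
setGeneric("assignmentCounts", function(x) standardGeneric("assignmentCounts"))

#' @rdname accessors
#' @export
setGeneric("conflictCount", function(x) standardGeneric("conflictCount"))

#' @rdname accessors
#' @export
setGeneric("mobilityCounts", function(x) standardGeneric("mobilityCounts"))

#' @rdname foreignReadProportion
#' @export
setGeneric("foreignReadProportion", function(x, ...) standardGeneric("foreignReadProportion"))
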