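#' Number of taxa
#' @param x an object with taxa
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' Number of alignment sites
#' @param x an object with sites
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Taxon labels
#' @param x an object with taxa
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Character matrix of an alignment
#' @param x a PhyloAlignment
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Posterior predictive p-value
#' @param x an AdequacyResult
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Adequacy decision
#' @param x an AdequacyResult
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))

#' Subsets of a partition scheme
#' @param x a PartitionScheme
#' @export
setGeneric("subsets", function(x) standardGeneric("subsets"))

#' Canonical splits
#' @param x a BipartitionSet
#' @export
setGeneric("splits", function(x) standardGeneric("splits"))
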