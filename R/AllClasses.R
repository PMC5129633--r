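#' @import methods
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "-", "?", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Multiple sequence alignment container
#'
#' A rectangular character matrix over the nucleotide alphabet (plus gap
#' \code{-}, missing \code{?}/\code{N} and IUPAC ambiguity codes), one row per
#' taxon. \code{U} is normalized to \code{T} and lowercase to uppercase on
#' construction.
#'
#' @slot seqs character matrix, rows named by taxon.
#'
#' @export
setClass("PhyloAlignment", representation(seqs = "matrix"))

setValidity("PhyloAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  taxa <- rownames(m)
  if (is.null(taxa) || any(!nzchar(taxa)))
    return("taxon labels must be non-empty")
  if (anyDuplicated(taxa))
    return(paste("duplicate taxon labels:",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  bad <- setdiff(unique(as.vector(m)), DNA_ALPHABET)
  if (length(bad))
    return(paste("unknown characters:", paste(bad, collapse = ", ")))
  TRUE
})

#' Per-site annotation track
#'
#' Column metadata driving data-block construction: gene id, codon position
#' (1, 2, 3 or NA), secondary-structure class (stem/loop, rDNA genes only)
#' and protein-domain label.
#'
#' @slot gene character vector, one per site.
#' @slot codonPos integer vector (1:3 or NA).
#' @slot structClass character ("stem", "loop" or NA).
#' @slot domain character or NA.
#'
#' @export
setClass("SiteAnnotation",
         representation(gene = "character", codonPos = "integer",
                        structClass = "character", domain = "character"))

setValidity("SiteAnnotation", function(object) {
  n <- length(object@gene)
  if (length(object@codonPos) != n || length(object@structClass) != n ||
      length(object@domain) != n)
    return("all annotation vectors must have equal length")
  if (any(!is.na(object@codonPos) & !(object@codonPos %in% 1:3)))
    return("codonPos must be 1, 2, 3 or NA")
  if (any(!is.na(object@structClass) &
          !(object@structClass %in% c("stem", "loop"))))
    return("structClass must be 'stem', 'loop' or NA")
  if (any(!is.na(object@codonPos) & !is.na(object@structClass)))
    return("a site cannot carry both codon and stem/loop annotation")
  TRUE
})

#' Boolean site mask with provenance
#'
#' @slot keep logical vector, one per site; FALSE marks a dropped site.
#' @slot provenance label explaining why sites are dropped
#'   (\code{codon3_excl}, \code{gap20}, \code{adequacy_excl}, \code{user}).
#'
#' @export
setClass("SiteMask",
         representation(keep = "logical", provenance = "character"))

setValidity("SiteMask", function(object) {
  if (length(object@provenance) != 1L) return("provenance must be length 1")
  if (anyNA(object@keep)) return("keep must not contain NA")
  TRUE
})

#' GTR+Gamma substitution model
#'
#' General time-reversible model with discrete-gamma rate variation.
#' Exchangeabilities are stored normalized so the G-T rate equals 1; the rate
#' matrix is rescaled so the expected substitution rate at stationarity is 1.
#' No proportion-invariant term (using +I together with +G is deliberately
#' unsupported).
#'
#' @slot rates 6 positive exchangeabilities, order AC, AG, AT, CG, CT, GT.
#' @slot freqs 4 stationary base frequencies (A, C, G, T), sum 1.
#' @slot alpha gamma shape, > 0.
#' @slot ncat number of equal-probability gamma categories (default 4).
#'
#' @export
setClass("GTRGammaModel",
         representation(rates = "numeric", freqs = "numeric",
                        alpha = "numeric", ncat = "integer"))

setValidity("GTRGammaModel", function(object) {
  if (length(object@rates) != 6 || any(object@rates <= 0))
    return("rates must be 6 positive values")
  if (length(object@freqs) != 4 || any(object@freqs <= 0))
    return("freqs must be 4 positive values")
  if (abs(sum(object@freqs) - 1) > 1e-10)
    return("freqs must sum to 1")
  if (length(object@alpha) != 1 || object@alpha <= 0)
    return("alpha must be a single positive value")
  if (object@ncat < 1L) return("ncat must be >= 1")
  TRUE
})

#' Partition scheme
#'
#' A disjoint grouping of data blocks; each subset is analyzed under its own
#' substitution model. Subsets record the names of their constituent blocks
#' and the union of their (1-based) site indices.
#'
#' @slot subsets named list; each element is a list with components
#'   \code{blocks} (character) and \code{sites} (integer).
#'
#' @export
setClass("PartitionScheme", representation(subsets = "list"))

setValidity("PartitionScheme", function(object) {
  if (length(object@subsets) == 0) return("scheme must have >= 1 subset")
  if (is.null(names(object@subsets)) || anyDuplicated(names(object@subsets)))
    return("subsets must be uniquely named")
  all_sites <- unlist(lapply(object@subsets, `[[`, "sites"))
  if (anyDuplicated(all_sites)) {
    dup <- unique(all_sites[duplicated(all_sites)])
    return(paste("overlapping subsets: sites",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  TRUE
})

#' Prior specification for Bayesian inference
#'
#' Flat Dirichlet priors on exchangeabilities and base frequencies, an
#' exponential prior on the gamma shape, and either i.i.d. exponential or
#' compound Dirichlet (gamma on tree length, flat Dirichlet on proportions)
#' branch-length priors.
#'
#' @slot alphaRate rate of the exponential prior on the gamma shape.
#' @slot brlenPrior "exponential" or "compound_dirichlet".
#' @slot brlenRate rate of the exponential branch-length prior.
#' @slot treeLengthShape,treeLengthRate gamma hyperparameters of the compound
#'   Dirichlet tree-length prior.
#'
#' @export
setClass("PriorSpec",
         representation(alphaRate = "numeric", brlenPrior = "character",
                        brlenRate = "numeric", treeLengthShape = "numeric",
                        treeLengthRate = "numeric"))

setValidity("PriorSpec", function(object) {
  if (object@alphaRate <= 0) return("alphaRate must be positive")
  if (!(object@brlenPrior %in% c("exponential", "compound_dirichlet")))
    return("brlenPrior must be 'exponential' or 'compound_dirichlet'")
  if (object@brlenRate <= 0 || object@treeLengthShape <= 0 ||
      object@treeLengthRate <= 0)
    return("prior hyperparameters must be positive")
  TRUE
})

#' MCMC settings
#'
#' One generation is a sweep updating the exchangeabilities, frequencies,
#' gamma shape, a batch of branch lengths and the total tree length (plus an
#' NNI topology move when enabled).
#'
#' @slot ngen number of generations.
#' @slot samplefreq record a draw every samplefreq generations.
#' @slot nchains number of Metropolis-coupled chains.
#' @slot temp heating increment; chain i runs at heat 1/(1 + temp * i).
#' @slot burnin fraction of recorded draws discarded, in [0, 1).
#' @slot seed RNG seed.
#' @slot topologyMoves logical; propose NNI moves.
#'
#' @export
setClass("MCMCSettings",
         representation(ngen = "integer", samplefreq = "integer",
                        nchains = "integer", temp = "numeric",
                        burnin = "numeric", seed = "integer",
                        topologyMoves = "logical"))

setValidity("MCMCSettings", function(object) {
  if (object@ngen < object@samplefreq || object@samplefreq < 1L)
    return("need ngen >= samplefreq >= 1")
  if (object@burnin < 0 || object@burnin >= 1)
    return("burnin must be in [0, 1)")
  if (object@nchains < 1L) return("nchains must be >= 1")
  TRUE
})

#' Posterior sample
#'
#' Ordered post-burn-in draws of (GTR+Gamma model, tree, log-likelihood),
#' either from the internal sampler or assembled from an external parameter
#' trace plus a fixed tree.
#'
#' @slot models list of \code{GTRGammaModel} draws.
#' @slot trees list of \code{phylo} trees (one per draw, or a single tree
#'   recycled for external traces).
#' @slot lnL numeric log-likelihoods (NA allowed for external traces).
#' @slot source "internal" or "external".
#' @slot trace data.frame parameter trace (MrBayes .p layout).
#' @slot acceptance named numeric acceptance rates per move type.
#'
#' @export
setClass("PosteriorSample",
         representation(models = "list", trees = "list", lnL = "numeric",
                        source = "character", trace = "data.frame",
                        acceptance = "numeric"))

setValidity("PosteriorSample", function(object) {
  if (length(object@models) == 0) return("empty posterior sample")
  if (length(object@trees) != length(object@models))
    return("trees and models must have equal length")
  TRUE
})

#' Posterior predictive adequacy result for one partition
#'
#' @slot partition partition name.
#' @slot Tobs observed multinomial likelihood statistic.
#' @slot Trep replicate statistics, one per predictive simulation.
#' @slot pValue lower-tail rank p-value with add-one correction.
#' @slot decision "adequate" or "inadequate".
#' @slot nReps number of predictive replicates.
#' @slot settings list echoing alpha, tail rule, subsample size, seed.
#'
#' @export
setClass("AdequacyResult",
         representation(partition = "character", Tobs = "numeric",
                        Trep = "numeric", pValue = "numeric",
                        decision = "character", nReps = "integer",
                        settings = "list"))

setValidity("AdequacyResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("p-value must be in [0, 1]")
  if (length(object@Trep) < 1) return("need >= 1 replicate")
  if (object@nReps != length(object@Trep))
    return("nReps must equal length(Trep)")
  if (!(object@decision %in% c("adequate", "inadequate")))
    return("decision must be 'adequate' or 'inadequate'")
  TRUE
})

#' Canonical bipartition set of a tree
#'
#' Non-trivial splits of the leaf set, each stored canonically as the
#' lexicographically sorted smaller side (ties broken toward the
#' lexicographically smaller side).
#'
#' @slot splits character vector; each element is the sorted labels of one
#'   canonical side joined by "|".
#' @slot leaves the full leaf label set.
#'
#' @export
setClass("BipartitionSet",
         representation(splits = "character", leaves = "character"))

setValidity("BipartitionSet", function(object) {
  if (anyDuplicated(object@splits)) return("duplicate splits")
  TRUE
})

#' Synthetic study specification
#'
#' Describes a study-shaped multi-gene dataset: taxa, genes (rDNA with
#' stem/loop tracts, protein-coding with codon positions and domains),
#' per-block generating models or violation specs, whole gene-by-taxon
#' missingness and gap injection in rDNA loops.
#'
#' @slot nTaxa number of taxa.
#' @slot genes data.frame with columns name, kind ("rDNA"/"coding"), length,
#'   nDomains.
#' @slot blockModels named list: per-block \code{GTRGammaModel} or a
#'   violation spec list (see \code{\link{simulateViolation}}).
#' @slot missingFraction target fraction of gene-by-taxon cells blanked.
#' @slot gapColumnFraction per rDNA gene, fraction of loop columns receiving
#'   gaps.
#' @slot treeLengthMean mean of the exponential branch-length distribution.
#' @slot seed RNG seed.
#'
#' @export
setClass("StudySpec",
         representation(nTaxa = "integer", genes = "data.frame",
                        blockModels = "list", missingFraction = "numeric",
                        gapColumnFraction = "numeric",
                        treeLengthMean = "numeric", seed = "integer"))

setValidity("StudySpec", function(object) {
  g <- object@genes
  if (!all(c("name", "kind", "length", "nDomains") %in% names(g)))
    return("genes needs columns name, kind, length, nDomains")
  if (any(g$length <= 0)) return("gene lengths must be positive")
  coding <- g$kind == "coding"
  if (any(g$length[coding] %% 3 != 0))
    return("coding gene lengths must be divisible by 3")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    return("missingFraction must be in [0, 1)")
  TRUE
})
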