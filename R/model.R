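#' Construct a GTR+Gamma model
#'
#' Exchangeabilities are normalized so r(G-T) = 1 (traces using the
#' sum-to-one convention are converted on ingest); frequencies are
#' renormalized to the simplex. The rate matrix is always rescaled so the
#' expected substitution rate at stationarity equals 1, making branch lengths
#' expected substitutions per site.
#'
#' @param rates 6 positive exchangeabilities, order AC, AG, AT, CG, CT, GT.
#' @param freqs 4 base frequencies (A, C, G, T).
#' @param alpha gamma shape (> 0).
#' @param ncat number of equal-probability gamma categories.
#' @return a \code{GTRGammaModel}.
#' @examples
#' jc <- gtrGamma(rep(1, 6), rep(0.25, 4), alpha = 1)
#' rateMatrix(jc)
#' @export
gtrGamma <- function(rates = rep(1, 6), freqs = rep(0.25, 4), alpha = 1,
                     ncat = 4L) {
  if (any(rates <= 0)) stop("exchangeabilities must be positive")
  if (any(freqs <= 0)) {
    # guard for near-zero frequencies: floor and renormalize
    freqs <- pmax(freqs, 1e-8)
  }
  rates <- rates / rates[6]
  freqs <- freqs / sum(freqs)
  names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  names(freqs) <- c("A", "C", "G", "T")
  new("GTRGammaModel", rates = rates, freqs = freqs, alpha = alpha,
      ncat = as.integer(ncat))
}

#' @export
setMethod("show", "GTRGammaModel", function(object) {
  cat("GTR+Gamma model\n")
  cat("  rates:", paste(sprintf("%s=%.4g", names(object@rates),
                                object@rates), collapse = " "), "\n")
  cat("  freqs:", paste(sprintf("%s=%.4g", names(object@freqs),
                                object@freqs), collapse = " "), "\n")
  cat(sprintf("  alpha: %.4g (%d categories)\n", object@alpha, object@ncat))
})

#' GTR rate matrix
#'
#' Builds the 4x4 instantaneous rate matrix Q with Q_ij = r_ij * pi_j for
#' i != j, rows summing to zero, scaled so the expected rate
#' -sum(pi_i Q_ii) = 1. Satisfies detailed balance pi_i Q_ij = pi_j Q_ji.
#'
#' @param model a \code{GTRGammaModel}.
#' @return 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
rateMatrix <- function(model) {
  stopifnot(is(model, "GTRGammaModel"))
  r <- model@rates; p <- model@freqs
  Q <- matrix(0, 4, 4, dimnames = list(names(p), names(p)))
  Q["A", "C"] <- r["AC"] * p["C"]; Q["C", "A"] <- r["AC"] * p["A"]
  Q["A", "G"] <- r["AG"] * p["G"]; Q["G", "A"] <- r["AG"] * p["A"]
  Q["A", "T"] <- r["AT"] * p["T"]; Q["T", "A"] <- r["AT"] * p["A"]
  Q["C", "G"] <- r["CG"] * p["G"]; Q["G", "C"] <- r["CG"] * p["C"]
  Q["C", "T"] <- r["CT"] * p["T"]; Q["T", "C"] <- r["CT"] * p["C"]
  Q["G", "T"] <- r["GT"] * p["T"]; Q["T", "G"] <- r["GT"] * p["G"]
  diag(Q) <- -rowSums(Q)
  Q / sum(p * -diag(Q))
}

# eigen-decomposition of the symmetrized GTR matrix:
# B = D^{1/2} Q D^{-1/2} is symmetric; P(t) = A exp(L t) Ainv with
# A = D^{-1/2} V, Ainv = V' D^{1/2}
gtrEigen <- function(model) {
  Q <- rateMatrix(model)
  p <- unname(model@freqs)
  sp <- sqrt(p)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(lambda = e$values,
       A = diag(1 / sp) %*% e$vectors,
       Ainv = t(e$vectors) %*% diag(sp))
}

#' Discrete gamma category rates
#'
#' Equal-probability categories with the category mean as representative
#' rate (mean-1 exact by construction): boundaries are Gamma(alpha, alpha)
#' quantiles and the category mean is computed from the Gamma(alpha+1, alpha)
#' CDF.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return k positive rates with mean 1.
#' @export
discreteGammaRates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be positive")
  if (k < 1) stop("k must be >= 1")
  if (k == 1L) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                          rate = alpha)
  cdf1 <- stats::pgamma(bounds, shape = alpha + 1, rate = alpha)
  k * diff(cdf1)
}

#' Transition probability matrix
#'
#' P(t * rate) = exp(Q t rate), computed by eigen-decomposition of the
#' symmetrized rate matrix. Rows sum to 1; P(0) is the identity.
#'
#' @param model a \code{GTRGammaModel}.
#' @param t branch length (>= 0, expected substitutions per site).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 4x4 stochastic matrix.
#' @export
transitionProbs <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  e <- gtrEigen(model)
  P <- e$A %*% diag(exp(e$lambda * t * rate)) %*% e$Ainv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(names(model@freqs), names(model@freqs))
  P
}

# --- alignment -> compressed site patterns -------------------------------

# returns list(tippart = 4 x npat x ntip array, weights, index) for the taxa
# in `order` (defaults to alignment order)
.site_patterns <- function(aln, order = NULL) {
  m <- alignmentMatrix(aln)
  if (!is.null(order)) m <- m[order, , drop = FALSE]
  key <- do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  idx <- match(key, unique(key))
  weights <- as.numeric(tabulate(idx))
  first <- which(!duplicated(idx))
  ntip <- nrow(m)
  npat <- length(first)
  tp <- array(0, dim = c(4, npat, ntip))
  for (tip in seq_len(ntip))
    tp[, , tip] <- .partial_lookup[, m[tip, first]]
  list(tippart = tp, weights = weights, index = idx)
}

# tree prepared for the C++ core: postorder edges, brlen aligned to edges,
# tip indices matched to the given taxon order
.prep_tree <- function(tree, taxa_order) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tr <- ape::reorder.phylo(tree, "postorder")
  perm <- match(tr$tip.label, taxa_order)
  if (anyNA(perm))
    stop("leaf without sequence: ",
         paste(tr$tip.label[is.na(perm)], collapse = ", "))
  # relabel tip node ids so that tip i corresponds to taxa_order[i]
  edge <- tr$edge
  tipmap <- integer(max(edge))
  tipmap[seq_along(perm)] <- perm
  ntip <- length(tr$tip.label)
  internal <- edge > ntip
  edge[!internal] <- tipmap[edge[!internal]]
  list(edge = edge, brlen = tr$edge.length, ntip = ntip)
}

#' Log-likelihood of an alignment on a tree under GTR+Gamma
#'
#' Felsenstein pruning over compressed site patterns with equal-weight
#' discrete-gamma rate mixing. Gap, \code{?} and \code{N} characters (and
#' IUPAC codes, partially) are treated as missing data via partial-likelihood
#' masks; a column of all-missing characters contributes exactly 0.
#' Numerical underflow is handled by per-node scaling accumulated in log
#' space.
#'
#' @param aln a \code{PhyloAlignment}; its taxa must include all tree leaves.
#' @param tree an ape \code{phylo} with branch lengths.
#' @param model a \code{GTRGammaModel}.
#' @param persite return the per-site log-likelihood vector instead of the
#'   sum.
#' @return total log-likelihood (or per-site vector).
#' @export
logLikelihood <- function(aln, tree, model, persite = FALSE) {
  stopifnot(is(aln, "PhyloAlignment"), is(model, "GTRGammaModel"))
  missing_taxa <- setdiff(tree$tip.label, taxa(aln))
  if (length(missing_taxa))
    stop("leaf without sequence: ", paste(missing_taxa, collapse = ", "))
  aln <- aln[tree$tip.label, ]
  pat <- .site_patterns(aln)
  pt <- .prep_tree(tree, taxa(aln))
  e <- gtrEigen(model)
  rates <- discreteGammaRates(model@alpha, model@ncat)
  out <- .cpp_pruning_loglik(pt$edge, pt$ntip, as.numeric(pat$tippart),
                             pat$weights, unname(model@freqs), e$A, e$Ainv,
                             e$lambda, pt$brlen, rates, persite)
  if (persite) out[pat$index] else out[1]
}

#' Simulate an alignment on a tree under GTR+Gamma
#'
#' Root states are drawn from the stationary frequencies; states evolve down
#' each branch under the transition probabilities, with one gamma category
#' drawn per site. Deterministic given the seed.
#'
#' @param tree an ape \code{phylo} with branch lengths.
#' @param model a \code{GTRGammaModel}.
#' @param n_sites number of sites (>= 1).
#' @param seed optional RNG seed; when NULL the current RNG state is used.
#' @return a \code{PhyloAlignment} with the tree's tip labels as taxa.
#' @export
simulateAlignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(is(model, "GTRGammaModel"), n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tr$tip.label)
  rates <- discreteGammaRates(model@alpha, model@ncat)
  e <- gtrEigen(model)
  states <- .cpp_simulate_states(tr$edge, ntip, tr$edge.length, e$A, e$Ainv,
                                 e$lambda, unname(model@freqs), rates,
                                 n_sites)
  m <- matrix(c("A", "C", "G", "T")[states], nrow = ntip)
  rownames(m) <- tr$tip.label
  phyloAlignment(m)
}
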