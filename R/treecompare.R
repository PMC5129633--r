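# canonical form of one side of a split within a leaf set: the smaller side;
# on ties the side whose sorted-label string is lexicographically smaller
.canonical_split <- function(side, leaves) {
  other <- setdiff(leaves, side)
  side <- sort(side); other <- sort(other)
  pick <- if (length(side) < length(other)) side
          else if (length(other) < length(side)) other
          else if (paste(side, collapse = "|") <=
                   paste(other, collapse = "|")) side else other
  paste(pick, collapse = "|")
}

#' Canonical bipartition set of a tree
#'
#' Every internal edge of the (implicitly unrooted) tree defines a split of
#' the leaf set; trivial splits (single leaves and their complements) are
#' excluded, and splits are stored canonically so re-rooting leaves the set
#' unchanged. For an unrooted fully resolved n-leaf tree the set has n - 3
#' elements.
#'
#' @param tree an ape \code{phylo}.
#' @return a \code{BipartitionSet}.
#' @export
bipartitions <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  leaves <- tree$tip.label
  n <- length(leaves)
  out <- character(0)
  if (n >= 4) {
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    # prop.part lists the leaf set of every internal node (first = root)
    for (cl in pp) {
      side <- labs[cl]
      if (length(side) <= 1 || length(side) >= n - 1) next
      out <- c(out, .canonical_split(side, leaves))
    }
    out <- unique(out)
  }
  new("BipartitionSet", splits = out, leaves = sort(leaves))
}

#' @describeIn bipartitions split accessor
#' @param x a BipartitionSet
#' @export
setMethod("splits", "BipartitionSet", function(x) x@splits)

#' @export
setMethod("show", "BipartitionSet", function(object) {
  cat("BipartitionSet:", length(object@splits), "non-trivial splits on",
      length(object@leaves), "leaves\n")
})

#' Shared-clade percentage between two trees
#'
#' 100 * |S_a intersect S_b| / ((|S_a| + |S_b|) / 2), where S are the
#' non-trivial canonical split sets. The average-of-counts denominator
#' accommodates trees of unequal resolution (e.g. an ML tree vs a consensus
#' with polytomies); "min" and "reference" denominators are available.
#' Two trees with no non-trivial splits (stars) count as 100.
#'
#' @param tree_a,tree_b ape \code{phylo} trees on identical leaf sets.
#' @param denominator "average", "min" or "reference" (= tree_a's count).
#' @param prune_to_common prune both trees to their common leaves first
#'   (default FALSE: mismatched leaf sets are an error).
#' @return percentage in [0, 100].
#' @export
sharedCladePercentage <- function(tree_a, tree_b,
                                  denominator = c("average", "min",
                                                  "reference"),
                                  prune_to_common = FALSE) {
  denominator <- match.arg(denominator)
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    if (!prune_to_common)
      stop("leaf-set mismatch (set prune_to_common = TRUE to restrict to ",
           "shared leaves)")
    common <- intersect(tree_a$tip.label, tree_b$tip.label)
    if (length(common) < 4) stop("fewer than 4 shared leaves")
    tree_a <- ape::keep.tip(tree_a, common)
    tree_b <- ape::keep.tip(tree_b, common)
  }
  sa <- splits(bipartitions(tree_a))
  sb <- splits(bipartitions(tree_b))
  denom <- switch(denominator,
                  average = (length(sa) + length(sb)) / 2,
                  min = min(length(sa), length(sb)),
                  reference = length(sa))
  if (denom == 0) return(100)
  100 * length(intersect(sa, sb)) / denom
}

# split relative frequencies in a tree sample: named numeric vector
.split_freqs <- function(trees) {
  counts <- list()
  for (tr in trees) {
    for (s in splits(bipartitions(tr)))
      counts[[s]] <- (counts[[s]] %||% 0) + 1
  }
  if (!length(counts)) return(stats::setNames(numeric(0), character(0)))
  unlist(counts) / length(trees)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average standard deviation of split frequencies (ASDSF)
#'
#' Convergence diagnostic between independent tree samples: over all splits
#' whose relative frequency reaches \code{min_freq} in at least one sample,
#' the average of the across-sample standard deviation (n-1 denominator) of
#' the split frequencies. Values below 0.05 are conventionally taken as
#' acceptable topological convergence.
#'
#' @param sample_a,sample_b \code{multiPhylo} (or lists of \code{phylo}) on
#'   identical leaf sets.
#' @param min_freq inclusion threshold (default 0.10, the MrBayes
#'   convention).
#' @return the ASDSF (0 when no split passes the filter, with a warning).
#' @export
asdsf <- function(sample_a, sample_b, min_freq = 0.10) {
  if (!length(sample_a) || !length(sample_b)) stop("empty tree sample")
  if (!setequal(sample_a[[1]]$tip.label, sample_b[[1]]$tip.label))
    stop("leaf-set mismatch between samples")
  fa <- .split_freqs(sample_a)
  fb <- .split_freqs(sample_b)
  all_splits <- union(names(fa), names(fb))
  va <- stats::setNames(rep(0, length(all_splits)), all_splits)
  vb <- va
  va[names(fa)] <- fa
  vb[names(fb)] <- fb
  use <- va >= min_freq | vb >= min_freq
  if (!any(use)) {
    warning("no split reaches min_freq in either sample; ASDSF defined as 0")
    return(0)
  }
  mean(vapply(which(use), function(i) stats::sd(c(va[i], vb[i])), 0))
}

#' Monophyly check
#'
#' TRUE iff the taxa form one side of some split of the tree (singletons are
#' monophyletic by convention). Also reports the size of the smallest clade
#' (split side) containing the taxa.
#'
#' @param tree an ape \code{phylo}.
#' @param taxa_set character vector of leaf labels (non-empty subset).
#' @return list(monophyletic = logical, smallest_clade_size = integer).
#' @export
monophylyCheck <- function(tree, taxa_set) {
  unknown <- setdiff(taxa_set, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (!length(taxa_set)) stop("empty taxon set")
  n <- length(tree$tip.label)
  taxa_set <- unique(taxa_set)
  if (length(taxa_set) == 1)
    return(list(monophyletic = TRUE, smallest_clade_size = 1L))
  if (length(taxa_set) == n)
    return(list(monophyletic = TRUE, smallest_clade_size = n))
  # sides of all splits, trivial included, in both orientations
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(cl) labs[cl])
  sides <- c(sides, lapply(sides, function(s) setdiff(labs, s)),
             as.list(labs))
  target <- sort(taxa_set)
  mono <- any(vapply(sides, function(s)
    length(s) == length(target) && identical(sort(s), target), TRUE))
  containing <- Filter(function(s) all(target %in% s), sides)
  smallest <- if (length(containing))
    min(vapply(containing, length, 0L)) else n
  list(monophyletic = mono, smallest_clade_size = as.integer(smallest))
}

#' Clade presence/absence matrix across analyses
#'
#' For every non-trivial clade (canonical split) of the reference tree,
#' records its presence in each other tree, and computes the pairwise
#' shared-clade percentages over all trees.
#'
#' @param reference ape \code{phylo}.
#' @param others named list of ape \code{phylo} on the same leaf set.
#' @param prune_to_common restrict every comparison to shared leaves.
#' @return list with \code{presence} (logical matrix, clades x analyses),
#'   \code{shared} (numeric matrix of pairwise percentages).
#' @export
cladePresenceMatrix <- function(reference, others, prune_to_common = FALSE) {
  if (is.null(names(others)) || any(!nzchar(names(others))))
    names(others) <- paste0("analysis", seq_along(others))
  ref_splits <- splits(bipartitions(reference))
  presence <- matrix(FALSE, length(ref_splits), length(others),
                     dimnames = list(ref_splits, names(others)))
  for (nm in names(others)) {
    os <- splits(bipartitions(others[[nm]]))
    presence[, nm] <- ref_splits %in% os
  }
  all_trees <- c(list(reference = reference), others)
  k <- length(all_trees)
  shared <- matrix(100, k, k,
                   dimnames = list(names(all_trees), names(all_trees)))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      shared[i, j] <- shared[j, i] <- sharedCladePercentage(
        all_trees[[i]], all_trees[[j]], prune_to_common = prune_to_common)
    }
  }
  list(presence = presence, shared = shared)
}
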