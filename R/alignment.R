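#' Construct a PhyloAlignment
#'
#' Normalizes input on ingest: lowercase is uppercased and RNA \code{U}
#' becomes \code{T}. \code{?} and \code{N} both denote fully missing data;
#' \code{-} is kept distinct as a gap (the gap-fraction filter and the
#' adequacy gap-stripping step depend on the distinction).
#'
#' @param seqs character matrix (rows = taxa) or named character vector /
#'   named list of equal-length sequence strings.
#' @return a \code{PhyloAlignment}.
#' @examples
#' aln <- phyloAlignment(c(t1 = "ACGT", t2 = "AC-T"))
#' nSites(aln)
#' @export
phyloAlignment <- function(seqs) {
  if (is.character(seqs) && !is.matrix(seqs)) seqs <- as.list(seqs)
  if (is.list(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by taxon")
    lens <- vapply(seqs, nchar, 1L)
    if (length(unique(lens)) > 1) {
      bad <- names(seqs)[lens != lens[1]][1]
      stop("ragged alignment: taxon '", bad, "' has ", lens[lens != lens[1]][1],
           " characters, expected ", lens[1])
    }
    m <- do.call(rbind, lapply(seqs, function(s)
      strsplit(s, "", fixed = TRUE)[[1]]))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  seqs[] <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  new("PhyloAlignment", seqs = seqs)
}

#' @describeIn phyloAlignment number of taxa
#' @param x a PhyloAlignment
#' @export
setMethod("nTaxa", "PhyloAlignment", function(x) nrow(x@seqs))

#' @describeIn phyloAlignment number of sites
#' @export
setMethod("nSites", "PhyloAlignment", function(x) ncol(x@seqs))

#' @describeIn phyloAlignment taxon labels
#' @export
setMethod("taxa", "PhyloAlignment", function(x) rownames(x@seqs))

#' @describeIn phyloAlignment the underlying character matrix
#' @export
setMethod("alignmentMatrix", "PhyloAlignment", function(x) x@seqs)

#' @export
setMethod("show", "PhyloAlignment", function(object) {
  cat("PhyloAlignment:", nTaxa(object), "taxa x", nSites(object), "sites\n")
  n <- min(5L, nTaxa(object))
  w <- min(60L, nSites(object))
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s%s\n", taxa(object)[i],
                paste(object@seqs[i, seq_len(w)], collapse = ""),
                if (nSites(object) > w) "..." else ""))
  if (nTaxa(object) > n) cat("  ...\n")
})

#' Subset an alignment by taxa and/or sites
#'
#' @param x a PhyloAlignment
#' @param i taxon selector (names, indices or logical)
#' @param j site selector (indices or logical)
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "PhyloAlignment", function(x, i, j, ..., drop = FALSE) {
  m <- x@seqs
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  new("PhyloAlignment", seqs = m)
})

MISSING_CHARS <- c("?", "N")
AMBIG_PARTIALS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `?` = c("A", "C", "G", "T"),
  `-` = c("A", "C", "G", "T"))

# 4 x 18 lookup of tip partial-likelihood masks, columns named by character
.partial_lookup <- local({
  m <- sapply(AMBIG_PARTIALS, function(st) {
    v <- numeric(4)
    v[match(st, c("A", "C", "G", "T"))] <- 1
    v
  })
  rownames(m) <- c("A", "C", "G", "T")
  m
})

# logical: is the character real data (not gap/missing)?
isDataChar <- function(ch) !(ch %in% c("-", "?", "N"))
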