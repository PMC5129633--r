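#' Construct a per-site annotation track
#'
#' @param gene character vector of gene ids, one per site.
#' @param codonPos integer (1, 2, 3) or NA per site; must cycle 1,2,3 within
#'   each coding region.
#' @param structClass "stem", "loop" or NA per site (rDNA genes only).
#' @param domain domain label or NA per site.
#' @return a \code{SiteAnnotation}.
#' @export
siteAnnotation <- function(gene, codonPos = NA_integer_,
                           structClass = NA_character_,
                           domain = NA_character_) {
  n <- length(gene)
  new("SiteAnnotation", gene = as.character(gene),
      codonPos = rep_len(as.integer(codonPos), n),
      structClass = rep_len(as.character(structClass), n),
      domain = rep_len(as.character(domain), n))
}

#' @describeIn siteAnnotation number of annotated sites
#' @param x a SiteAnnotation
#' @export
setMethod("nSites", "SiteAnnotation", function(x) length(x@gene))

#' @export
setMethod("show", "SiteAnnotation", function(object) {
  cat("SiteAnnotation:", nSites(object), "sites,",
      length(unique(object@gene)), "genes\n")
  for (g in unique(object@gene)) {
    i <- object@gene == g
    kind <- if (any(!is.na(object@structClass[i]))) "rDNA" else "coding"
    cat(sprintf("  %-8s %5d sites (%s)\n", g, sum(i), kind))
  }
})

#' Read an annotation track from a tab-delimited per-site table
#'
#' Expected columns: \code{gene}, \code{codon_pos}, \code{struct_class},
#' \code{domain} (empty string or NA for none), one row per site.
#'
#' @param path file path.
#' @return a \code{SiteAnnotation}.
#' @export
readAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  siteAnnotation(gene = df$gene, codonPos = df$codon_pos,
                 structClass = df$struct_class, domain = df$domain)
}

#' Write an annotation track
#' @param annot a SiteAnnotation.
#' @param path output path.
#' @export
writeAnnotation <- function(annot, path) {
  df <- data.frame(gene = annot@gene, codon_pos = annot@codonPos,
                   struct_class = annot@structClass, domain = annot@domain)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a priori data blocks from annotations
#'
#' rDNA genes yield one block per structure class (gene x stem, gene x loop);
#' protein-coding genes yield gene x domain x codon position (or
#' gene x codon position where no domain is annotated). The union of blocks
#' covers all annotated sites and blocks are mutually disjoint. An optional
#' merge map collapses candidate blocks into a coarser a priori layout.
#'
#' @param annot a \code{SiteAnnotation}.
#' @param merge optional named list: new block name -> character vector of
#'   candidate block names to merge.
#' @return named list of blocks, each a list with \code{name}, \code{gene},
#'   \code{sites} (1-based integer site indices).
#' @export
buildBlocks <- function(annot, merge = NULL) {
  stopifnot(is(annot, "SiteAnnotation"))
  validObject(annot)
  n <- nSites(annot)
  if (n == 0) return(list())
  key <- character(n)
  for (i in seq_len(n)) {
    g <- annot@gene[i]
    if (!is.na(annot@structClass[i])) {
      key[i] <- paste(g, annot@structClass[i], sep = "_")
    } else if (!is.na(annot@codonPos[i])) {
      key[i] <- if (!is.na(annot@domain[i]))
        paste(g, annot@domain[i], annot@codonPos[i], sep = "_")
      else paste(g, annot@codonPos[i], sep = "_")
    } else {
      key[i] <- g
    }
  }
  blocks <- lapply(split(seq_len(n), key), function(sites)
    list(name = key[sites[1]], gene = annot@gene[sites[1]],
         sites = as.integer(sites)))
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  blocks <- blocks[order(names(blocks))]
  if (!is.null(merge)) {
    for (newname in names(merge)) {
      members <- merge[[newname]]
      missing_b <- setdiff(members, names(blocks))
      if (length(missing_b))
        stop("merge refers to unknown blocks: ",
             paste(missing_b, collapse = ", "))
      genes <- unique(vapply(blocks[members], `[[`, "", "gene"))
      merged <- list(name = newname,
                     gene = if (length(genes) == 1) genes else
                       paste(genes, collapse = "+"),
                     sites = sort(unlist(lapply(blocks[members], `[[`,
                                                "sites"), use.names = FALSE)))
      blocks <- blocks[setdiff(names(blocks), members)]
      blocks[[newname]] <- merged
    }
    blocks <- blocks[order(names(blocks))]
  }
  blocks
}

#' Site mask excluding third codon positions of one gene
#'
#' @param annot a \code{SiteAnnotation}.
#' @param gene gene to mask (e.g. "COI").
#' @return a \code{SiteMask} with provenance "codon3_excl".
#' @export
excludeCodon3 <- function(annot, gene) {
  stopifnot(is(annot, "SiteAnnotation"))
  in_gene <- annot@gene == gene
  if (!any(in_gene)) {
    warning("gene '", gene, "' not present in annotation; no-op mask")
    return(new("SiteMask", keep = rep(TRUE, nSites(annot)),
               provenance = "codon3_excl"))
  }
  if (all(is.na(annot@codonPos[in_gene])))
    stop("gene '", gene, "' has no codon annotation")
  drop <- in_gene & !is.na(annot@codonPos) & annot@codonPos == 3L
  new("SiteMask", keep = !drop, provenance = "codon3_excl")
}

#' Site mask dropping gap-rich columns
#'
#' A site is dropped iff its gap fraction is strictly greater than the
#' threshold ("more than" semantics). The gap fraction counts \code{-}
#' characters; \code{?}/\code{N} are counted too only when
#' \code{count_missing = TRUE} (default FALSE: the rule is about gaps).
#' Fractions are computed over the full taxon set of the alignment passed in
#' (i.e. after any taxon filtering).
#'
#' @param aln a \code{PhyloAlignment}.
#' @param threshold fraction in [0, 1).
#' @param count_missing also count \code{?} and \code{N}.
#' @return a \code{SiteMask} with provenance "gap20".
#' @export
gapFractionFilter <- function(aln, threshold = 0.20, count_missing = FALSE) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  m <- alignmentMatrix(aln)
  chars <- if (count_missing) c("-", "?", "N") else "-"
  frac <- colMeans(matrix(m %in% chars, nrow = nrow(m)))
  new("SiteMask", keep = frac <= threshold, provenance = "gap20")
}

#' Taxa with data in at least min_genes genes
#'
#' A taxon "has" a gene when at least one site in the gene's span is a real
#' character (not \code{-}, \code{?} or \code{N}).
#'
#' @param aln a \code{PhyloAlignment}.
#' @param gene_spans named list of integer site vectors partitioning the
#'   sites by gene.
#' @param min_genes minimal number of covered genes.
#' @return character vector of kept taxon labels.
#' @export
taxonCompletenessFilter <- function(aln, gene_spans, min_genes) {
  if (min_genes > length(gene_spans))
    stop("min_genes (", min_genes, ") exceeds number of genes (",
         length(gene_spans), ")")
  m <- alignmentMatrix(aln)
  covered <- sapply(gene_spans, function(sites)
    apply(m[, sites, drop = FALSE], 1, function(row) any(isDataChar(row))))
  keep <- rowSums(covered) >= min_genes
  taxa(aln)[keep]
}

#' Apply masks and partition exclusions to assemble a dataset variant
#'
#' Drops the sites rejected by any mask and all sites of excluded blocks,
#' remaps the surviving blocks to the new coordinates, and returns an audit
#' table attributing every dropped site to exactly one provenance label
#' (masks take precedence in the order given, then "adequacy_excl" for
#' excluded blocks), so that audit counts + retained length = original
#' length. Taxon order and characters are never altered.
#'
#' @param aln a \code{PhyloAlignment}.
#' @param blocks block list from \code{\link{buildBlocks}}.
#' @param masks list of \code{SiteMask}.
#' @param excluded_blocks character vector of block names to drop entirely.
#' @return list with \code{alignment}, \code{blocks} (remapped),
#'   \code{audit} (data.frame label/sites), \code{kept_sites} (original
#'   indices).
#' @export
assembleDataset <- function(aln, blocks, masks = list(),
                            excluded_blocks = character(0)) {
  n <- nSites(aln)
  for (msk in masks) {
    if (length(msk@keep) != n)
      stop("mask of wrong length: ", length(msk@keep), " vs ", n, " sites")
  }
  unknown <- setdiff(excluded_blocks, names(blocks))
  if (length(unknown))
    stop("excluded blocks not in block list: ",
         paste(unknown, collapse = ", "))
  dropped_by <- rep(NA_character_, n)
  for (msk in masks) {
    newly <- !msk@keep & is.na(dropped_by)
    dropped_by[newly] <- msk@provenance
  }
  excl_sites <- unlist(lapply(blocks[excluded_blocks], `[[`, "sites"),
                       use.names = FALSE)
  newly <- is.na(dropped_by) & seq_len(n) %in% excl_sites
  dropped_by[newly] <- "adequacy_excl"
  keep <- is.na(dropped_by)
  kept_sites <- which(keep)
  remap <- integer(n)
  remap[kept_sites] <- seq_along(kept_sites)
  new_blocks <- list()
  for (nm in setdiff(names(blocks), excluded_blocks)) {
    bs <- blocks[[nm]]$sites
    bs <- bs[keep[bs]]
    if (!length(bs)) next
    new_blocks[[nm]] <- list(name = nm, gene = blocks[[nm]]$gene,
                             sites = remap[bs])
  }
  audit_labels <- c(vapply(masks, function(m) m@provenance, ""),
                    "adequacy_excl")
  audit <- data.frame(
    label = c(audit_labels, "retained"),
    sites = c(vapply(audit_labels, function(lb)
      sum(dropped_by == lb, na.rm = TRUE), 0L), length(kept_sites)))
  list(alignment = aln[, kept_sites], blocks = new_blocks, audit = audit,
       kept_sites = kept_sites)
}

#' Combine site masks (logical AND of keep flags)
#' @param ... SiteMask objects.
#' @param provenance label for the combined mask.
#' @return a \code{SiteMask}.
#' @export
combineMasks <- function(..., provenance = "user") {
  masks <- list(...)
  keep <- Reduce(`&`, lapply(masks, function(m) m@keep))
  new("SiteMask", keep = keep, provenance = provenance)
}
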