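#' Read a multiple sequence alignment
#'
#' Supports FASTA, PHYLIP (sequential or interleaved, relaxed taxon names)
#' and NEXUS DATA blocks. Parsing is delegated to \pkg{ape}; the result is
#' validated against the alignment contract (rectangular, unique non-empty
#' taxon labels, known characters) with informative errors. If the NEXUS file
#' carries a SETS block, its charsets are attached as attribute
#' \code{"charsets"} (a named list of integer site vectors, 1-based).
#'
#' @param path file path.
#' @param format one of "fasta", "phylip", "nexus".
#' @return a \code{\link{phyloAlignment}} (with optional \code{charsets}
#'   attribute for NEXUS input).
#' @export
readAlignment <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- switch(format,
    fasta = {
      x <- ape::read.FASTA(path)
      lapply(as.character(x), paste, collapse = "")
    },
    phylip = .read_phylip(path),
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, paste, collapse = "")
    })
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  aln <- phyloAlignment(seqs)
  if (format == "nexus") {
    cs <- .parse_nexus_charsets(readLines(path, warn = FALSE))
    if (length(cs)) attr(aln, "charsets") <- cs
  }
  aln
}

# PHYLIP reader: tries sequential then interleaved; on failure produces a
# ragged-row diagnostic naming the offending taxon.
.read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2 || anyNA(hdr))
    stop("malformed PHYLIP header: ", lines[1])
  ntax <- hdr[1]; nchar_exp <- hdr[2]
  body <- lines[-1]
  nonblank <- body[nzchar(trimws(body))]
  seq_try <- tryCatch(
    ape::read.dna(path, format = "sequential", as.character = TRUE),
    error = function(e) NULL)
  if (is.null(seq_try) && length(nonblank) > ntax)
    seq_try <- tryCatch(
      ape::read.dna(path, format = "interleaved", as.character = TRUE),
      error = function(e) NULL)
  if (is.null(seq_try)) {
    # diagnostic scan (sequential layout): name + sequence per line
    for (ln in utils::head(nonblank, ntax)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      seqlen <- sum(nchar(parts[-1]))
      if (seqlen != nchar_exp)
        stop("ragged PHYLIP row: taxon '", parts[1], "' has ", seqlen,
             " characters, header says ", nchar_exp)
    }
    stop("failed to parse PHYLIP file: ", path)
  }
  if (ncol(seq_try) != nchar_exp)
    stop("PHYLIP dimensions mismatch: header says ", nchar_exp,
         " sites, found ", ncol(seq_try))
  stats::setNames(
    lapply(seq_len(nrow(seq_try)), function(i)
      paste(seq_try[i, ], collapse = "")),
    rownames(seq_try))
}

# parse "charset name = 1-30 45 50-60\3;" lines from a SETS (or ASSUMPTIONS)
# block; returns named list of 1-based integer vectors
.parse_nexus_charsets <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  hits <- regmatches(txt,
    gregexpr("(?i)charset\\s+[^=;]+=[^;]+;", txt, perl = TRUE))[[1]]
  out <- list()
  for (h in hits) {
    h <- sub(";$", "", h)
    kv <- strsplit(h, "=")[[1]]
    name <- trimws(sub("(?i)charset", "", kv[1], perl = TRUE))
    out[[name]] <- .parse_range_spec(trimws(kv[2]))
  }
  out
}

# "1-30 45 50-60\3" -> integer site vector (1-based inclusive, stride aware)
.parse_range_spec <- function(spec) {
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  sites <- integer(0)
  for (tk in toks) {
    stride <- 1L
    if (grepl("\\\\", tk)) {
      parts <- strsplit(tk, "\\\\")[[1]]
      stride <- as.integer(parts[2]); tk <- parts[1]
    }
    if (grepl("-", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1]])
      sites <- c(sites, seq(ab[1], ab[2], by = stride))
    } else sites <- c(sites, as.integer(tk))
  }
  sort(unique(sites))
}

#' Write an alignment to file
#'
#' Output is re-readable by \code{\link{readAlignment}} with exact round-trip
#' of the character matrix and taxon order. \code{?} and IUPAC codes are
#' preserved in every format.
#'
#' @param aln a PhyloAlignment.
#' @param path output path.
#' @param format one of "fasta", "phylip", "nexus".
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(aln, "PhyloAlignment"))
  m <- alignmentMatrix(aln)
  switch(format,
    fasta = {
      con <- file(path, "w")
      on.exit(close(con))
      for (i in seq_len(nrow(m))) {
        writeLines(paste0(">", rownames(m)[i]), con)
        writeLines(paste(m[i, ], collapse = ""), con)
      }
    },
    phylip = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste(nrow(m), ncol(m)), con)
      for (i in seq_len(nrow(m)))
        writeLines(paste0(rownames(m)[i], "  ",
                          paste(m[i, ], collapse = "")), con)
    },
    nexus = {
      lst <- stats::setNames(
        lapply(seq_len(nrow(m)), function(i) m[i, ]), rownames(m))
      ape::write.nexus.data(lst, path, format = "dna", interleaved = FALSE)
    })
  invisible(path)
}

#' Read trees from a Newick or NEXUS file
#'
#' All trees in one file must share an identical leaf-label set; polytomies
#' are accepted.
#'
#' @param path file path.
#' @param format "newick" or "nexus".
#' @return an ape \code{multiPhylo} (also for a single tree).
#' @export
readTrees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- switch(format,
    newick = ape::read.tree(path),
    nexus = ape::read.nexus(path))
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees),
                                                     class = "multiPhylo"))
  if (is.null(trees) || length(trees) == 0)
    stop("no parsable trees in ", path)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    tl <- trees[[i]]$tip.label
    if (anyDuplicated(tl))
      stop("duplicate leaf label in tree ", i, ": ",
           paste(unique(tl[duplicated(tl)]), collapse = ", "))
    if (!identical(sort(tl), ref))
      stop("leaf-set mismatch: tree ", i,
           " does not match the first tree's leaves")
    if (!is.null(trees[[i]]$edge.length) && any(trees[[i]]$edge.length < 0))
      stop("negative branch length in tree ", i)
  }
  trees
}

#' Write trees
#'
#' @param trees a phylo or multiPhylo.
#' @param path output path.
#' @param format "newick" or "nexus".
#' @export
writeTrees <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick") ape::write.tree(trees, path)
  else ape::write.nexus(trees, file = path)
  invisible(path)
}

# canonical internal names for GTR trace columns
.TRACE_SYNONYMS <- local({
  syn <- c(
    "Gen" = "Gen", "generation" = "Gen",
    "LnL" = "LnL", "lnl" = "LnL", "loglik" = "LnL",
    "TL" = "TL", "tl" = "TL", "treelength" = "TL",
    "r(A<->C)" = "r_AC", "r_AC" = "r_AC", "rAC" = "r_AC",
    "r(A<->G)" = "r_AG", "r_AG" = "r_AG", "rAG" = "r_AG",
    "r(A<->T)" = "r_AT", "r_AT" = "r_AT", "rAT" = "r_AT",
    "r(C<->G)" = "r_CG", "r_CG" = "r_CG", "rCG" = "r_CG",
    "r(C<->T)" = "r_CT", "r_CT" = "r_CT", "rCT" = "r_CT",
    "r(G<->T)" = "r_GT", "r_GT" = "r_GT", "rGT" = "r_GT",
    "pi(A)" = "pi_A", "pi_A" = "pi_A", "piA" = "pi_A",
    "pi(C)" = "pi_C", "pi_C" = "pi_C", "piC" = "pi_C",
    "pi(G)" = "pi_G", "pi_G" = "pi_G", "piG" = "pi_G",
    "pi(T)" = "pi_T", "pi_T" = "pi_T", "piT" = "pi_T",
    "alpha" = "alpha", "shape" = "alpha")
  names(syn) <- tolower(names(syn))
  syn
})

#' Read a MrBayes-style .p parameter trace
#'
#' Tab-delimited trace with a header row (an optional leading
#' \code{[ID: ...]} comment line is skipped). Column-name synonyms
#' (\code{r(A<->C)} vs \code{r_AC}, \code{pi(A)} vs \code{pi_A}) are
#' normalized. Base-frequency rows are renormalized to sum to 1 (tolerance
#' 1e-6 after normalization). Burn-in is NOT applied here.
#'
#' @param path file path.
#' @return data.frame with normalized column names; required columns are the
#'   six exchangeabilities, four frequencies and \code{alpha}.
#' @export
readParamTrace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("^\\s*\\[", lines[1])) lines <- lines[-1]
  header <- strsplit(lines[1], "\t")[[1]]
  canon <- .TRACE_SYNONYMS[tolower(trimws(header))]
  canon[is.na(canon)] <- trimws(header)[is.na(canon)]
  required <- c("r_AC", "r_AG", "r_AT", "r_CG", "r_CT", "r_GT",
                "pi_A", "pi_C", "pi_G", "pi_T", "alpha")
  missing_cols <- setdiff(required, canon)
  if (length(missing_cols))
    stop("required parameter absent from trace: ",
         paste(missing_cols, collapse = ", "))
  rows <- strsplit(lines[-1], "\t")
  mat <- matrix(NA_real_, length(rows), length(canon),
                dimnames = list(NULL, canon))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v) || length(v) != length(canon)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric cell at trace row ", i, ", column ",
           if (!is.na(bad)) canon[bad] else "?")
    }
    mat[i, ] <- v
  }
  df <- as.data.frame(mat)
  pis <- as.matrix(df[, c("pi_A", "pi_C", "pi_G", "pi_T")])
  rs <- rowSums(pis)
  if (any(abs(rs - 1) > 0.01))
    stop("frequency rows deviate from simplex by more than 1%")
  df[, c("pi_A", "pi_C", "pi_G", "pi_T")] <- pis / rs
  df
}

#' Assemble a PosteriorSample from an external trace and a fixed tree
#'
#' When an external MrBayes-style trace carries no sampled trees, a
#' user-supplied fixed tree (with branch lengths) stands in for every draw.
#'
#' @param trace data.frame from \code{\link{readParamTrace}}.
#' @param tree an ape \code{phylo} with branch lengths.
#' @param burnin fraction of leading draws discarded (default 0.5).
#' @param ncat gamma categories for the reconstructed models.
#' @return a \code{PosteriorSample} with source "external".
#' @export
traceToPosterior <- function(trace, tree, burnin = 0.5, ncat = 4L) {
  stopifnot(is.data.frame(trace), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("fixed tree must have branch lengths")
  keep <- trace[seq.int(floor(nrow(trace) * burnin) + 1, nrow(trace)), ,
                drop = FALSE]
  if (nrow(keep) < 1) stop("no draws remain after burn-in")
  models <- lapply(seq_len(nrow(keep)), function(i) {
    gtrGamma(rates = as.numeric(keep[i, c("r_AC", "r_AG", "r_AT",
                                          "r_CG", "r_CT", "r_GT")]),
             freqs = as.numeric(keep[i, c("pi_A", "pi_C", "pi_G", "pi_T")]),
             alpha = keep$alpha[i], ncat = ncat)
  })
  lnl <- if ("LnL" %in% names(keep)) keep$LnL else rep(NA_real_, nrow(keep))
  new("PosteriorSample", models = models,
      trees = rep(list(tree), nrow(keep)), lnL = lnl,
      source = "external", trace = keep,
      acceptance = stats::setNames(numeric(0), character(0)))
}

#' Write a MrBayes-style .p parameter trace
#'
#' @param trace data.frame (e.g. the \code{trace} slot of a
#'   \code{PosteriorSample}).
#' @param path output path.
#' @export
writeParamTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[ID: phybpa parameter trace]", con)
  writeLines(paste(names(trace), collapse = "\t"), con)
  utils::write.table(trace, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a partition scheme to a RAxML or NEXUS sets file
#'
#' Ranges are emitted 1-based inclusive, comma-separated, with codon stride
#' notation where a subset is an every-third-site set (\code{\\3} in the
#' RAxML dialect, \code{step 3} NEXUS comment form is not used; NEXUS charset
#' stride uses the same backslash convention).
#'
#' @param scheme a \code{PartitionScheme}.
#' @param path output path.
#' @param dialect "raxml" or "nexus_sets".
#' @export
writePartitionFile <- function(scheme, path,
                               dialect = c("raxml", "nexus_sets")) {
  dialect <- match.arg(dialect)
  stopifnot(is(scheme, "PartitionScheme"))
  validObject(scheme)
  lines <- character(0)
  if (dialect == "nexus_sets") lines <- c("#NEXUS", "begin sets;")
  for (nm in names(scheme@subsets)) {
    spec <- .format_range_spec(scheme@subsets[[nm]]$sites)
    lines <- c(lines, if (dialect == "raxml")
      paste0("DNA, ", nm, " = ", spec)
      else paste0("  charset ", nm, " = ", spec, ";"))
  }
  if (dialect == "nexus_sets") lines <- c(lines, "end;")
  writeLines(lines, path)
  invisible(path)
}

# integer sites -> "a-b, c, d-e\3" (1-based inclusive, stride 1 or 3)
.format_range_spec <- function(sites) {
  sites <- sort(unique(as.integer(sites)))
  segs <- character(0)
  i <- 1L
  n <- length(sites)
  while (i <= n) {
    for (stride in c(1L, 3L)) {
      j <- i
      while (j < n && sites[j + 1L] - sites[j] == stride) j <- j + 1L
      if (j > i || stride == 3L) {
        run_len <- j - i + 1L
        if (stride == 1L && run_len >= 2L) {
          segs <- c(segs, paste0(sites[i], "-", sites[j]))
          i <- j + 1L
          break
        }
        if (stride == 3L && run_len >= 2L) {
          segs <- c(segs, paste0(sites[i], "-", sites[j], "\\3"))
          i <- j + 1L
          break
        }
      }
      if (stride == 3L) {  # singleton
        segs <- c(segs, as.character(sites[i]))
        i <- i + 1L
      }
    }
  }
  paste(segs, collapse = ", ")
}
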