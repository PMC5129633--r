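#' Default study-shaped gene table
#'
#' Eight gene regions mirroring a mixed rDNA / protein-coding supermatrix:
#' four rDNA genes with stem/loop structure and four protein-coding genes
#' with codon structure, two of them with multiple protein domains.
#'
#' @return data.frame with columns name, kind, length, nDomains.
#' @export
defaultStudyGenes <- function() {
  data.frame(
    name = c("16S", "18S", "28SD2", "28SD3", "COI", "Wg", "CAD", "TP1"),
    kind = c("rDNA", "rDNA", "rDNA", "rDNA",
             "coding", "coding", "coding", "coding"),
    length = c(450L, 400L, 250L, 200L, 420L, 300L, 480L, 360L),
    nDomains = c(0L, 0L, 0L, 0L, 1L, 1L, 4L, 2L),
    stringsAsFactors = FALSE)
}

#' Synthetic study specification
#'
#' Defines the conditions of a study-shaped dataset: a shared true tree,
#' per-block GTR+Gamma generating models (drawn once, seeded, from realistic
#' ranges unless supplied), whole gene-by-taxon missingness (incomplete
#' sequencing) and gap injection in rDNA loop regions. Defaults: 30 taxa,
#' 8 genes / ~2.9 kb, 40\% missing cells — the desk-scale shape of a large
#' multi-gene supermatrix after per-gene subsampling.
#'
#' @param nTaxa number of taxa (default 30).
#' @param genes gene table (see \code{\link{defaultStudyGenes}}).
#' @param blockModels optional named list keyed by block name, each either a
#'   \code{GTRGammaModel} or a violation spec list (fields as in
#'   \code{\link{simulateViolation}}); unspecified blocks get seeded random
#'   GTR+Gamma models.
#' @param missingFraction target fraction of blanked cells (default 0.4).
#' @param gapColumnFraction fraction of rDNA loop columns receiving gaps
#'   (default 0.15).
#' @param treeLengthMean mean of the exponential branch-length distribution
#'   (default 0.08 substitutions/site).
#' @param seed RNG seed.
#' @return a \code{StudySpec}.
#' @export
studySpec <- function(nTaxa = 30L, genes = defaultStudyGenes(),
                      blockModels = list(), missingFraction = 0.4,
                      gapColumnFraction = 0.15, treeLengthMean = 0.08,
                      seed = 1L) {
  new("StudySpec", nTaxa = as.integer(nTaxa), genes = genes,
      blockModels = blockModels, missingFraction = missingFraction,
      gapColumnFraction = gapColumnFraction,
      treeLengthMean = treeLengthMean, seed = as.integer(seed))
}

# seeded random GTR+Gamma model within realistic ranges: transition bias,
# moderate composition skew, alpha in (0.3, 2)
.random_gtr <- function(ncat = 4L) {
  r <- c(1, 4, 1, 1, 4, 1) * exp(stats::rnorm(6, 0, 0.3))
  f <- .rdirichlet1(rep(20, 4))
  gtrGamma(r, f, alpha = stats::runif(1, 0.3, 2), ncat = ncat)
}

# annotation layout for one spec: returns SiteAnnotation plus per-gene spans
.study_annotation <- function(spec) {
  genes <- spec@genes
  total <- sum(genes$length)
  gene_v <- character(total)
  codon_v <- rep(NA_integer_, total)
  struct_v <- rep(NA_character_, total)
  domain_v <- rep(NA_character_, total)
  offset <- 0L
  spans <- list()
  for (gi in seq_len(nrow(genes))) {
    len <- genes$length[gi]
    idx <- offset + seq_len(len)
    gene_v[idx] <- genes$name[gi]
    if (genes$kind[gi] == "rDNA") {
      # alternating stem/loop tracts, geometric-ish lengths, seeded
      cls <- character(0)
      cur <- "stem"
      while (length(cls) < len) {
        tract <- 5L + stats::rgeom(1, 1 / 10)
        cls <- c(cls, rep(cur, tract))
        cur <- if (cur == "stem") "loop" else "stem"
      }
      struct_v[idx] <- cls[seq_len(len)]
    } else {
      codon_v[idx] <- rep_len(1:3, len)
      nd <- genes$nDomains[gi]
      if (nd > 1L) {
        chunk <- len %/% nd  # gene lengths chosen divisible by 3 * nDomains
        domain_v[idx] <- rep(paste0("D", seq_len(nd)),
                             times = c(rep(chunk, nd - 1),
                                       len - chunk * (nd - 1)))
      }
    }
    spans[[genes$name[gi]]] <- idx
    offset <- offset + len
  }
  list(annot = siteAnnotation(gene_v, codon_v, struct_v, domain_v),
       spans = spans)
}

#' Simulate a study-shaped dataset with known truth
#'
#' Draws one shared true tree (Yule topology, i.i.d. exponential branch
#' lengths), simulates each a priori data block under its declared
#' GTR+Gamma model or violation process, annotates rDNA genes with
#' alternating stem/loop tracts and coding genes with codon positions and
#' domain boundaries, blanks whole gene-by-taxon cells with \code{?} until
#' the target missing fraction is met (each taxon keeps at least one gene),
#' and injects alignment gaps into rDNA loop columns. Deterministic given
#' the spec's seed.
#'
#' @param spec a \code{StudySpec}.
#' @return list with \code{alignment}, \code{annotation}, \code{tree},
#'   \code{truth} (data.frame: block, gene, generator, violating),
#'   \code{blocks}, \code{gene_spans}.
#' @export
simulateStudy <- function(spec) {
  stopifnot(is(spec, "StudySpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nTaxa
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", seq_len(n))
  tree$edge.length <- stats::rexp(nrow(tree$edge),
                                  rate = 1 / spec@treeLengthMean)
  lay <- .study_annotation(spec)
  annot <- lay$annot
  blocks <- buildBlocks(annot)
  total <- nSites(annot)

  mat <- matrix("?", n, total, dimnames = list(tree$tip.label, NULL))
  truth <- list()
  for (nm in names(blocks)) {
    bl <- blocks[[nm]]
    gen <- spec@blockModels[[nm]]
    if (is.null(gen)) gen <- .random_gtr()
    if (is(gen, "GTRGammaModel")) {
      sim <- simulateAlignment(tree, gen, length(bl$sites))
      generator <- "gtrgamma"; violating <- FALSE
    } else {
      sim <- simulateViolation(tree, gen, length(bl$sites))
      generator <- gen$type; violating <- TRUE
    }
    mat[, bl$sites] <- alignmentMatrix(sim)[tree$tip.label, ]
    truth[[nm]] <- data.frame(block = nm, gene = bl$gene,
                              generator = generator, violating = violating)
  }

  # whole gene-by-taxon missingness
  spans <- lay$spans
  gene_names <- names(spans)
  target <- spec@missingFraction
  if (target > 0) {
    glens <- vapply(spans, length, 0L)
    achievable <- sum(vapply(seq_len(n), function(i)
      sum(glens) - min(glens), 0)) / (n * total)
    if (target > achievable)
      stop("infeasible missing fraction: would blank a taxon entirely")
    cand <- expand.grid(taxon = seq_len(n), gene = gene_names,
                        stringsAsFactors = FALSE)
    cand <- cand[sample.int(nrow(cand)), ]
    remaining <- rep(length(gene_names), n)
    blanked <- 0
    for (ci in seq_len(nrow(cand))) {
      if (blanked / (n * total) >= target) break
      tx <- cand$taxon[ci]; gn <- cand$gene[ci]
      if (remaining[tx] <= 1L) next
      mat[tx, spans[[gn]]] <- "?"
      remaining[tx] <- remaining[tx] - 1L
      blanked <- blanked + length(spans[[gn]])
    }
  }

  # gap injection in rDNA loop columns
  is_loop <- !is.na(annot@structClass) & annot@structClass == "loop"
  for (gn in spec@genes$name[spec@genes$kind == "rDNA"]) {
    cols <- intersect(spans[[gn]], which(is_loop))
    ngap <- round(spec@gapColumnFraction * length(cols))
    if (ngap < 1) next
    gap_cols <- sample(cols, ngap)
    for (cl in gap_cols) {
      q <- stats::runif(1, 0.05, 0.6)
      rows <- sample.int(n, max(1, round(q * n)))
      cell <- mat[rows, cl]
      mat[rows, cl] <- ifelse(cell == "?", "?", "-")
    }
  }

  list(alignment = phyloAlignment(mat), annotation = annot, tree = tree,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       blocks = blocks, gene_spans = spans)
}

#' Simulate sequences under a deliberately model-violating process
#'
#' Three violation types, each specified as a list with a \code{type} field:
#' \describe{
#'   \item{nonstationary_composition}{fields \code{modelA}, \code{modelB},
#'     optional \code{clade} (leaf labels): the tree evolves under A, but
#'     every branch inside the designated clade (default: the clade closest
#'     to half the taxa) switches to the composition-shifted model B.}
#'   \item{covarion_switch}{fields \code{model}, \code{s_on}, \code{s_off},
#'     \code{p_on_root}: each site toggles between an evolving ("on") and a
#'     frozen ("off") state along the tree via a two-state switch process;
#'     simulated exactly as an 8-state Markov chain (base x on/off).}
#'   \item{partition_mixture}{fields \code{models} (list of 2), optional
#'     \code{trees} (list of 2), \code{weights}: each site is drawn from one
#'     mixture component.}
#' }
#'
#' @param tree ape \code{phylo} with branch lengths.
#' @param vspec violation spec list (see Details).
#' @param n_sites number of sites.
#' @param seed optional RNG seed.
#' @return a \code{PhyloAlignment}.
#' @export
simulateViolation <- function(tree, vspec, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  switch(vspec$type,
    nonstationary_composition =
      .sim_nonstationary(tree, vspec, n_sites),
    covarion_switch = .sim_covarion(tree, vspec, n_sites),
    partition_mixture = .sim_mixture(tree, vspec, n_sites),
    stop("unknown violation type: ", vspec$type))
}

# clade whose size is closest to half the taxa (deterministic)
.half_clade <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sizes <- lengths(pp)
  n <- length(labs)
  ok <- which(sizes >= 2 & sizes <= n - 2)
  if (!length(ok)) stop("tree has no internal clade to designate")
  best <- ok[which.min(abs(sizes[ok] - n / 2))]
  labs[pp[[best]]]
}

.sim_nonstationary <- function(tree, vspec, n_sites) {
  modelA <- vspec$modelA
  stopifnot(is(modelA, "GTRGammaModel"))
  # one or more designated clades, each with its own shifted model; the
  # single-clade form (modelB [+ clade]) is the common case
  clades <- vspec$clades
  modelsB <- vspec$modelsB
  if (is.null(clades)) {
    clades <- list(vspec$clade %||% .half_clade(tree))
    modelsB <- list(vspec$modelB)
  }
  stopifnot(length(clades) == length(modelsB))
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  edge_model <- integer(nrow(tr$edge))  # 0 = background A
  for (ci in seq_along(clades)) {
    clade <- clades[[ci]]
    missing_t <- setdiff(clade, tr$tip.label)
    if (length(missing_t))
      stop("designated clade absent from tree: ",
           paste(missing_t, collapse = ", "))
    stopifnot(is(modelsB[[ci]], "GTRGammaModel"))
    mrca <- if (length(clade) == 1) match(clade, tr$tip.label) else
      ape::getMRCA(tr, clade)
    in_clade <- c(mrca, .nodeDescendants(tr, mrca))
    edge_model[tr$edge[, 2] %in% in_clade] <- ci
  }
  eigs <- c(list(gtrEigen(modelA)), lapply(modelsB, gtrEigen))
  ratesA <- discreteGammaRates(modelA@alpha, modelA@ncat)
  site_cat <- sample.int(modelA@ncat, n_sites, replace = TRUE)
  nnode_tot <- max(tr$edge)
  root <- tr$edge[1, 1]
  states <- matrix(0L, nnode_tot, n_sites)
  states[root, ] <- sample.int(4, n_sites, TRUE, prob = unname(modelA@freqs))
  rate_mult <- vspec$rate_mult %||% 1  # rate acceleration in shifted clades
  for (ed in seq_len(nrow(tr$edge))) {
    par <- tr$edge[ed, 1]; chi <- tr$edge[ed, 2]
    e <- eigs[[edge_model[ed] + 1L]]
    t_eff <- tr$edge.length[ed] * (if (edge_model[ed] > 0) rate_mult else 1)
    for (k in seq_len(modelA@ncat)) {
      idx <- which(site_cat == k)
      if (!length(idx)) next
      P <- e$A %*% diag(exp(e$lambda * t_eff * ratesA[k])) %*%
        e$Ainv
      P[P < 0] <- 0; P <- P / rowSums(P)
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(idx))
      ps <- states[par, idx]
      states[chi, idx] <- 1L + (u > cum[cbind(ps, 1L)]) +
        (u > cum[cbind(ps, 2L)]) + (u > cum[cbind(ps, 3L)])
    }
  }
  m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), , drop = FALSE]],
              nrow = ntip, dimnames = list(tr$tip.label, NULL))
  phyloAlignment(m)
}

# two large disjoint clades (greedy, sizes near n/3), for opposite shifts
.two_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  sizes <- lengths(pp)
  ok <- which(sizes >= 3 & sizes <= ceiling(n / 2))
  ok <- ok[order(abs(sizes[ok] - n / 3))]
  first <- labs[pp[[ok[1]]]]
  for (i in ok[-1]) {
    cand <- labs[pp[[i]]]
    if (!length(intersect(cand, first))) return(list(first, cand))
  }
  stop("no two disjoint clades found")
}

# all descendants (tips and internals) of a node, by edge sweep
.nodeDescendants <- function(tree, node) {
  edge <- tree$edge
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    kids <- edge[edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids[kids > length(tree$tip.label)]
  }
  out
}

.sim_covarion <- function(tree, vspec, n_sites) {
  model <- vspec$model
  stopifnot(is(model, "GTRGammaModel"))
  s_on <- vspec$s_on %||% 0.2    # rate off -> on
  s_off <- vspec$s_off %||% 0.2  # rate on -> off
  p_on <- vspec$p_on_root %||% (s_on / (s_on + s_off))
  Q <- rateMatrix(model)
  rates <- discreteGammaRates(model@alpha, model@ncat)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode_tot <- max(tr$edge)
  root <- tr$edge[1, 1]
  site_cat <- sample.int(model@ncat, n_sites, replace = TRUE)
  # 8 states: 1..4 = on-{A,C,G,T}, 5..8 = off-{A,C,G,T}
  build_R8 <- function(rate) {
    R <- matrix(0, 8, 8)
    R[1:4, 1:4] <- Q * rate
    diag(R[1:4, 1:4]) <- 0
    R[cbind(1:4, 5:8)] <- s_off
    R[cbind(5:8, 1:4)] <- s_on
    diag(R) <- -rowSums(R)
    R
  }
  states <- matrix(0L, nnode_tot, n_sites)
  base0 <- sample.int(4, n_sites, TRUE, prob = unname(model@freqs))
  on0 <- stats::runif(n_sites) < p_on
  states[root, ] <- base0 + 4L * (!on0)
  for (ed in seq_len(nrow(tr$edge))) {
    par <- tr$edge[ed, 1]; chi <- tr$edge[ed, 2]
    for (k in seq_len(model@ncat)) {
      idx <- which(site_cat == k)
      if (!length(idx)) next
      P <- as.matrix(Matrix::expm(build_R8(rates[k]) * tr$edge.length[ed]))
      P[P < 0] <- 0; P <- P / rowSums(P)
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(idx))
      ps <- states[par, idx]
      ns <- rep(1L, length(idx))
      for (col in 1:7) ns <- ns + (u > cum[cbind(ps, col)])
      states[chi, idx] <- ns
    }
  }
  base <- ((states[seq_len(ntip), , drop = FALSE] - 1L) %% 4L) + 1L
  m <- matrix(c("A", "C", "G", "T")[base], nrow = ntip,
              dimnames = list(tr$tip.label, NULL))
  phyloAlignment(m)
}

.sim_mixture <- function(tree, vspec, n_sites) {
  models <- vspec$models
  weights <- vspec$weights %||% rep(1 / length(models), length(models))
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  trees <- vspec$trees %||% rep(list(tree), length(models))
  comp <- sample.int(length(models), n_sites, TRUE, prob = weights)
  m <- matrix(NA_character_, length(tree$tip.label), n_sites,
              dimnames = list(sort(tree$tip.label), NULL))
  for (ci in seq_along(models)) {
    idx <- which(comp == ci)
    if (!length(idx)) next
    sim <- simulateAlignment(trees[[ci]], models[[ci]], length(idx))
    m[, idx] <- alignmentMatrix(sim)[rownames(m), ]
  }
  phyloAlignment(m)
}

#' Deterministic micro-fixtures for tests and examples
#'
#' \describe{
#'   \item{gapgrid}{10 taxa x 20 sites; column j carries j - 1 gaps, so a
#'     20\% gap filter keeps exactly the columns with at most 2 gaps.}
#'   \item{coi9}{4 taxa x 9 coding sites annotated as COI codons 1,2,3;
#'     third-position exclusion keeps 6 sites.}
#'   \item{twinsplit}{two 5-leaf trees one NNI apart; they share 1 of their
#'     2 non-trivial splits each, i.e. 50\%.}
#' }
#'
#' @return named list of fixtures.
#' @export
makeToyFixtures <- function() {
  bases <- c("A", "C", "G", "T")
  m <- matrix("", 10, 20)
  for (j in 1:20) {
    col <- rep(bases[((j - 1) %% 4) + 1], 10)
    ngap <- min(j - 1, 10)
    if (ngap > 0) col[seq_len(ngap)] <- "-"
    m[, j] <- col
  }
  rownames(m) <- sprintf("g%02d", 1:10)
  gapgrid <- phyloAlignment(m)

  coi <- phyloAlignment(c(a = "ACGTACGTA", b = "ACGTACGTC",
                          c = "ACGAACGTA", d = "ACGTACTTA"))
  coi_annot <- siteAnnotation(gene = rep("COI", 9), codonPos = rep(1:3, 3))

  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:1,(D:1,E:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,B:1,(D:1,E:1):1);")

  list(gapgrid = gapgrid, coi9 = list(aln = coi, annot = coi_annot),
       twinsplit = list(t1, t2))
}

#' Ten-partition adequacy benchmark with six model-violating partitions
#'
#' Builds a study-shaped concatenation of 10 equal-length partitions on one
#' shared tree: 4 conforming partitions simulated under seeded random
#' GTR+Gamma models, and 6 violating partitions — one strong nonstationary
#' composition shift (extreme AT-rich background, one clade shifted toward
#' balanced composition with rate acceleration, on a fast gene), two slow
#' covarion switch processes, and three two-component tree-scale mixtures
#' (a frozen component plus a fast component, the classic invariant-site
#' excess that a discrete gamma cannot absorb). The truth table labels each
#' partition, so adequacy decisions can be scored for power and
#' specificity.
#'
#' @param n_taxa taxa (default 30).
#' @param sites_per_block sites per partition (default 750, a typical gene
#'   length).
#' @param seed RNG seed.
#' @return list with \code{alignment}, \code{scheme} (one subset per
#'   partition), \code{tree}, \code{truth} (data.frame: partition,
#'   generator, violating).
#' @export
simulatePowerBenchmark <- function(n_taxa = 30L, sites_per_block = 750L,
                                   seed = 1L) {
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / 0.03)
  scale_tree <- function(t, f) { t$edge.length <- t$edge.length * f; t }
  gc_model <- function(gc, alpha = 0.8)
    gtrGamma(c(1, 4, 1, 1, 4, 1),
             c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), alpha)
  jc_like <- function(alpha = 0.8)
    gtrGamma(c(1, 4, 1, 1, 4, 1), rep(0.25, 4), alpha)

  parts <- list(
    conf1 = list(tree = tr, model = .random_gtr()),
    conf2 = list(tree = tr, model = .random_gtr()),
    conf3 = list(tree = tr, model = .random_gtr()),
    conf4 = list(tree = tr, model = .random_gtr()),
    comp1 = list(tree = scale_tree(tr, 4),
                 v = list(type = "nonstationary_composition",
                          modelA = gc_model(0.05), modelB = gc_model(0.6),
                          rate_mult = 2)),
    cov1 = list(tree = tr,
                v = list(type = "covarion_switch", model = jc_like(1),
                         s_on = 0.04, s_off = 0.04, p_on_root = 0.30)),
    cov2 = list(tree = tr,
                v = list(type = "covarion_switch", model = jc_like(1),
                         s_on = 0.02, s_off = 0.02, p_on_root = 0.35)),
    mix1 = list(tree = tr,
                v = list(type = "partition_mixture",
                         models = list(jc_like(), jc_like()),
                         trees = list(scale_tree(tr, 1e-6),
                                      scale_tree(tr, 4)),
                         weights = c(0.5, 0.5))),
    mix2 = list(tree = tr,
                v = list(type = "partition_mixture",
                         models = list(jc_like(), jc_like()),
                         trees = list(scale_tree(tr, 1e-6),
                                      scale_tree(tr, 6)),
                         weights = c(0.45, 0.55))),
    mix3 = list(tree = tr,
                v = list(type = "partition_mixture",
                         models = list(jc_like(), jc_like()),
                         trees = list(scale_tree(tr, 1e-6),
                                      scale_tree(tr, 5)),
                         weights = c(0.5, 0.5))))

  mats <- list()
  truth <- list()
  blocks <- list()
  off <- 0L
  for (nm in names(parts)) {
    pt <- parts[[nm]]
    sim <- if (!is.null(pt$model)) simulateAlignment(pt$tree, pt$model,
                                                     sites_per_block)
           else simulateViolation(pt$tree, pt$v, sites_per_block)
    mats[[nm]] <- alignmentMatrix(sim)[tr$tip.label, ]
    violating <- is.null(pt$model)
    truth[[nm]] <- data.frame(
      partition = nm,
      generator = if (violating) pt$v$type else "gtrgamma",
      violating = violating)
    blocks[[nm]] <- list(name = nm, gene = nm,
                         sites = off + seq_len(sites_per_block))
    off <- off + sites_per_block
  }
  aln <- phyloAlignment(do.call(cbind, mats))
  list(alignment = aln, scheme = partitionScheme(blocks), tree = tr,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
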