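toy_annot <- function() {
  # one rDNA gene (6 sites: stem,stem,loop,loop,stem,stem) and one coding
  # gene (9 sites, codons 1..3, single domain)
  siteAnnotation(
    gene = c(rep("18S", 6), rep("COI", 9)),
    codonPos = c(rep(NA, 6), rep(1:3, 3)),
    structClass = c("stem", "stem", "loop", "loop", "stem", "stem",
                    rep(NA, 9)))
}

test_that("a priori blocks follow the rDNA stem/loop and codon rules", {
  blocks <- buildBlocks(toy_annot())
  expect_setequal(names(blocks),
                  c("18S_stem", "18S_loop", "COI_1", "COI_2", "COI_3"))
  expect_equal(blocks$`18S_loop`$sites, 3:4)
  expect_equal(blocks$COI_2$sites, c(8L, 11L, 14L))
  # blocks disjoint and covering
  all_sites <- sort(unname(unlist(lapply(blocks, `[[`, "sites"))))
  expect_equal(all_sites, 1:15)

  expect_length(buildBlocks(siteAnnotation(character(0))), 0)

  # domain x codon blocks and merging to a coarser layout
  annot <- siteAnnotation(gene = rep("CAD", 12), codonPos = rep(1:3, 4),
                          domain = rep(c("D1", "D2"), each = 6))
  b2 <- buildBlocks(annot)
  expect_length(b2, 6)
  merged <- buildBlocks(annot, merge = list(
    CAD_3 = c("CAD_D1_3", "CAD_D2_3")))
  expect_length(merged, 5)
  expect_equal(merged$CAD_3$sites, sort(c(seq(3, 6, 3), seq(9, 12, 3))))
})

test_that("conflicting stem/loop + codon annotation is rejected", {
  expect_error(
    buildBlocks(siteAnnotation(gene = "x", codonPos = 1L,
                               structClass = "stem")),
    "both")
})

test_that("third-codon exclusion drops exactly the targeted sites", {
  annot <- toy_annot()
  mask <- excludeCodon3(annot, "COI")
  expect_equal(which(!mask@keep), c(9L, 12L, 15L))
  expect_equal(mask@provenance, "codon3_excl")
  # mismatching gene: warning + no-op
  expect_warning(m2 <- excludeCodon3(annot, "Wg"), "not present")
  expect_true(all(m2@keep))
  # gene without codon annotation is an error
  expect_error(excludeCodon3(annot, "18S"), "no codon annotation")
})

test_that("gap filter uses a strict greater-than threshold", {
  m <- matrix("A", 10, 3)
  m[1:2, 1] <- "-"   # 20% gaps -> kept at 0.20
  m[1:3, 2] <- "-"   # 30% -> dropped
  m[, 3] <- "-"      # all gaps -> dropped
  rownames(m) <- sprintf("t%02d", 1:10)
  aln <- phyloAlignment(m)
  mask <- gapFractionFilter(aln, 0.20)
  expect_equal(mask@keep, c(TRUE, FALSE, FALSE))
  # threshold 0: any gap drops the site
  expect_equal(gapFractionFilter(aln, 0)@keep, c(FALSE, FALSE, FALSE))
  # '?' only counts when requested
  m2 <- matrix("A", 10, 1); m2[1:5, 1] <- "?"
  rownames(m2) <- sprintf("t%02d", 1:10)
  expect_true(gapFractionFilter(phyloAlignment(m2), 0.2)@keep)
  expect_false(gapFractionFilter(phyloAlignment(m2), 0.2,
                                 count_missing = TRUE)@keep)
  expect_error(gapFractionFilter(aln, 1), "threshold")
})

test_that("gapgrid fixture: 20% rule keeps exactly the <=2-gap columns", {
  fx <- makeToyFixtures()
  mask <- gapFractionFilter(fx$gapgrid, 0.20)
  expect_equal(which(mask@keep), 1:3)
})

test_that("taxon completeness filter equals a brute-force recount", {
  set.seed(42)
  spans <- split(1:80, rep(1:8, each = 10))
  names(spans) <- paste0("g", 1:8)
  m <- matrix(sample(c("A", "C", "G", "T"), 20 * 80, TRUE), 20, 80,
              dimnames = list(sprintf("t%02d", 1:20), NULL))
  # blank random gene x taxon cells
  for (i in 1:20) {
    nblank <- sample(0:7, 1)
    for (g in sample(8, nblank)) m[i, spans[[g]]] <- "?"
  }
  aln <- phyloAlignment(m)
  for (min_genes in c(1, 4, 5, 8)) {
    kept <- taxonCompletenessFilter(aln, spans, min_genes)
    brute <- rownames(m)[vapply(seq_len(20), function(i) {
      sum(vapply(spans, function(s)
        any(!(m[i, s] %in% c("-", "?", "N"))), TRUE)) >= min_genes
    }, TRUE)]
    expect_identical(kept, brute)
  }
  expect_error(taxonCompletenessFilter(aln, spans, 9), "exceeds")
})

test_that("dataset assembly remaps blocks, audits drops, preserves rows", {
  annot <- toy_annot()
  set.seed(7)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 15, TRUE), 6, 15,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  m[1:3, 4] <- "-"  # 50% gaps at site 4
  aln <- phyloAlignment(m)
  blocks <- buildBlocks(annot)
  masks <- list(excludeCodon3(annot, "COI"), gapFractionFilter(aln, 0.20))
  out <- assembleDataset(aln, blocks, masks,
                         excluded_blocks = "18S_stem")
  # audit sums to the original length
  expect_equal(sum(out$audit$sites), 15)
  expect_equal(out$audit$sites[out$audit$label == "codon3_excl"], 3)
  expect_equal(out$audit$sites[out$audit$label == "gap20"], 1)
  # 18S_stem covers 4 sites (positions 1, 2, 5, 6)
  expect_equal(out$audit$sites[out$audit$label == "adequacy_excl"], 4)
  expect_equal(nSites(out$alignment), 7)
  # row order and characters untouched
  expect_identical(taxa(out$alignment), taxa(aln))
  expect_identical(alignmentMatrix(out$alignment),
                   alignmentMatrix(aln)[, out$kept_sites])
  # excluded block absent, others remapped within bounds
  expect_false("18S_stem" %in% names(out$blocks))
  for (b in out$blocks)
    expect_true(all(b$sites >= 1 & b$sites <= 7))
  # wrong-length mask rejected
  expect_error(assembleDataset(aln, blocks,
                               list(new("SiteMask", keep = TRUE,
                                        provenance = "user"))),
               "wrong length")
})

test_that("masks compose commutatively", {
  annot <- toy_annot()
  set.seed(8)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 6 * 15, TRUE,
                     prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), 6, 15,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  aln <- phyloAlignment(m)
  m1 <- excludeCodon3(annot, "COI")
  m2 <- gapFractionFilter(aln, 0.20)
  expect_equal(combineMasks(m1, m2)@keep, combineMasks(m2, m1)@keep)
  a12 <- assembleDataset(aln, buildBlocks(annot), list(m1, m2))
  a21 <- assembleDataset(aln, buildBlocks(annot), list(m2, m1))
  expect_identical(alignmentMatrix(a12$alignment),
                   alignmentMatrix(a21$alignment))
})

test_that("annotation tables round-trip through TSV", {
  annot <- toy_annot()
  p <- tempfile()
  writeAnnotation(annot, p)
  back <- readAnnotation(p)
  expect_equal(back@gene, annot@gene)
  expect_equal(back@codonPos, annot@codonPos)
  expect_equal(back@structClass, annot@structClass)
})
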