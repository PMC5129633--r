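test_that("taxon subsampling is seeded, order-preserving, bounded", {
  set.seed(50)
  aln <- random_alignment(20, 30)
  sub <- subsampleTaxa(aln, 20, seed = 1)
  expect_identical(taxa(sub), taxa(aln))
  s1 <- subsampleTaxa(aln, 8, seed = 2)
  s2 <- subsampleTaxa(aln, 8, seed = 2)
  expect_identical(taxa(s1), taxa(s2))
  expect_length(unique(taxa(s1)), 8)
  # parent row order preserved
  expect_identical(taxa(s1), taxa(aln)[taxa(aln) %in% taxa(s1)])
  expect_error(subsampleTaxa(aln, 21), "exceeds")
})

test_that("gap stripping drops exactly the gap-containing columns", {
  m <- matrix("A", 4, 5, dimnames = list(letters[1:4], NULL))
  m[2, 2] <- "-"; m[4, 4] <- "-"; m[1, 5] <- "?"
  aln <- phyloAlignment(m)
  expect_equal(nSites(stripGapSites(aln)), 3)
  expect_equal(nSites(stripGapSites(aln, drop_missing = TRUE)), 2)
  clean <- random_alignment(4, 10)
  expect_identical(alignmentMatrix(stripGapSites(clean)),
                   alignmentMatrix(clean))
  allgap <- phyloAlignment(c(a = "--", b = "--"))
  expect_error(stripGapSites(allgap), "no sites remain")
})

test_that("multinomial statistic: formula cases and brute-force oracle", {
  # all sites identical -> T = 0
  same <- phyloAlignment(c(a = "AAAA", b = "CCCC"))
  expect_equal(multinomialStatistic(same), 0)
  # all patterns distinct -> N ln(1/N)
  dist4 <- phyloAlignment(c(a = "ACGT", b = "AAGG"))
  expect_equal(multinomialStatistic(dist4), 4 * log(1 / 4),
               tolerance = 1e-12)
  # counts {2,1,1}: 2 ln(1/2) + 2 ln(1/4)
  p211 <- phyloAlignment(c(a = "AACG", b = "CCAT", c = "GGTA"))
  expect_equal(multinomialStatistic(p211), 2 * log(0.5) + 2 * log(0.25),
               tolerance = 1e-12)
  expect_error(multinomialStatistic(phyloAlignment(c(a = "", b = ""))),
               "zero-length")

  set.seed(51)
  for (i in 1:25) {
    aln <- random_alignment(sample(3:10, 1), sample(5:50, 1),
                            gap_prob = 0.05, missing_prob = 0.05)
    expect_equal(multinomialStatistic(aln), bruteforce_T(aln),
                 tolerance = 1e-12)
  }
})

test_that("statistic is invariant to site and taxon storage order", {
  set.seed(52)
  aln <- random_alignment(6, 40)
  base <- multinomialStatistic(aln)
  expect_equal(multinomialStatistic(aln[, sample(40)]), base)
  expect_equal(multinomialStatistic(aln[sample(6), ]), base)
  expect_lte(base, 0)
})

test_that("posterior predictive p-value follows the add-one rank rule", {
  set.seed(53)
  tr <- random_tree(6, mean_brlen = 0.05)
  m <- gtrGamma(rep(1, 6), rep(0.25, 4), alpha = 1)
  aln <- simulateAlignment(tr, m, 100, seed = 54)
  post <- new("PosteriorSample", models = rep(list(m), 40),
              trees = rep(list(tr), 40), lnL = rep(NA_real_, 40),
              source = "external", trace = data.frame(),
              acceptance = stats::setNames(numeric(0), character(0)))
  res <- posteriorPredictive(aln, post, n_reps = 99, seed = 55)
  expect_equal(res@pValue,
               (1 + sum(res@Trep <= res@Tobs)) / 100)
  expect_equal(res@nReps, 99L)
  # p can never be exactly 0 or 1
  expect_gt(res@pValue, 0)
  expect_lte(res@pValue, 1)
  # determinism
  res2 <- posteriorPredictive(aln, post, n_reps = 99, seed = 55)
  expect_identical(res2@Trep, res@Trep)
  # p-value invariant under monotone transformation of the statistic: the
  # rank of exp(T/100) equals the rank of T
  expect_equal((1 + sum(exp(res@Trep / 100) <= exp(res@Tobs / 100))) / 100,
               res@pValue)
})

test_that("posterior lacking trees instructs the user to supply one", {
  m <- gtrGamma(rep(1, 6), rep(0.25, 4))
  post <- new("PosteriorSample", models = list(m), trees = list(NULL),
              lnL = NA_real_, source = "external", trace = data.frame(),
              acceptance = stats::setNames(numeric(0), character(0)))
  aln <- phyloAlignment(c(a = "ACGT", b = "ACGT"))
  expect_error(posteriorPredictive(aln, post, n_reps = 10),
               "fixed tree")
})

test_that("decision rule boundaries: two-tailed vs lower-tailed", {
  expect_equal(decideAdequacy(0.5), "adequate")
  expect_equal(decideAdequacy(0.5, tail = "lower"), "adequate")
  # p = 0.03 at alpha 0.05: adequate two-tailed, inadequate lower-tailed
  expect_equal(decideAdequacy(0.03, 0.05, "two"), "adequate")
  expect_equal(decideAdequacy(0.03, 0.05, "lower"), "inadequate")
  expect_equal(decideAdequacy(0.99, 0.05, "two"), "inadequate")
  expect_equal(decideAdequacy(0.01, 0.05, "two"), "inadequate")
  expect_error(decideAdequacy(0.5, alpha = 0), "alpha")
})

test_that("point-mass posterior gives calibrated (uniform) p-values", {
  # with the generating parameters known exactly, the replicate statistics
  # come from the true sampling distribution and the rank p-value is
  # uniform up to add-one discreteness
  set.seed(56)
  tr <- random_tree(10, mean_brlen = 0.03)
  m <- gtrGamma(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.25, 0.25), alpha = 0.8)
  post <- new("PosteriorSample", models = rep(list(m), 30),
              trees = rep(list(tr), 30), lnL = rep(NA_real_, 30),
              source = "external", trace = data.frame(),
              acceptance = stats::setNames(numeric(0), character(0)))
  ps <- vapply(1:40, function(i) {
    aln <- simulateAlignment(tr, m, 150)
    pValue(posteriorPredictive(aln, post, n_reps = 60, seed = 600 + i))
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("adequacy pipeline returns per-partition reports and a DT3 mask", {
  set.seed(57)
  tr <- random_tree(12, mean_brlen = 0.03)
  m <- gtrGamma(c(1, 4, 1, 1, 4, 1), rep(0.25, 4), alpha = 1)
  a1 <- alignmentMatrix(simulateAlignment(tr, m, 120, seed = 58))
  a2 <- alignmentMatrix(simulateAlignment(tr, m, 90, seed = 59))
  aln <- phyloAlignment(cbind(a1, a2[rownames(a1), ]))
  blocks <- list(p1 = list(name = "p1", gene = "g1", sites = 1:120),
                 p2 = list(name = "p2", gene = "g2", sites = 121:210))
  out <- runAdequacyPipeline(aln, partitionScheme(blocks),
                             settings = mcmcSettings(ngen = 400,
                                                     samplefreq = 5),
                             n_subsample = 10, n_reps = 50, seed = 60)
  expect_named(out$results, c("p1", "p2"))
  expect_s4_class(out$results$p1, "AdequacyResult")
  expect_equal(nrow(out$report), 2)
  expect_length(out$mask@keep, 210)
  expect_equal(out$mask@provenance, "adequacy_excl")
  # empty exclusion set -> mask keeps everything (DT3 == G20)
  if (!length(out$excluded)) expect_true(all(out$mask@keep))
  # report round-trips
  p <- tempfile(fileext = ".tsv")
  writeAdequacyReport(out$report, p)
  back <- read.delim(p)
  expect_equal(back$partition, out$report$partition)
  expect_true(file.exists(paste0(p, ".json")))
})
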