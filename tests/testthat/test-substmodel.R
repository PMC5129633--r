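test_that("GTR rate matrix: JC special case, stationarity, detailed balance", {
  jc <- gtrGamma(rep(1, 6), rep(0.25, 4))
  Q <- rateMatrix(jc)
  expect_equal(unname(Q[1, 2:4]), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(diag(Q)), rep(-1, 4), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:5) {
    m <- gtrGamma(runif(6, 0.2, 5), as.numeric(phybpa:::.rdirichlet1(rep(5, 4))),
                  alpha = runif(1, 0.2, 3))
    Q <- rateMatrix(m)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # normalization: expected rate 1
    expect_equal(sum(m@freqs * -diag(Q)), 1, tolerance = 1e-12)
    # stationarity pi Q = 0 and detailed balance
    expect_lt(max(abs(m@freqs %*% Q)), 1e-10)
    D <- diag(unname(m@freqs))
    expect_lt(max(abs(D %*% Q - t(D %*% Q))), 1e-12)
  }
})

test_that("discrete gamma rates: limits and quadrature oracle", {
  expect_equal(discreteGammaRates(1e6, 4), rep(1, 4), tolerance = 1e-3)
  expect_identical(discreteGammaRates(0.5, 1), 1)
  set.seed(2)
  for (alpha in c(0.2, 1, 3.7)) {
    r <- discreteGammaRates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-8)
    # quadrature oracle: mean of Gamma(alpha, alpha) within each
    # equal-probability band, by numerical integration
    qs <- qgamma(seq(0, 1, 0.25), alpha, alpha)
    oracle <- sapply(1:4, function(k) {
      4 * integrate(function(x) x * dgamma(x, alpha, alpha),
                    qs[k], qs[k + 1], rel.tol = 1e-10)$value
    })
    expect_equal(r, oracle, tolerance = 1e-6)
  }
  expect_error(discreteGammaRates(-1, 4), "positive")
})

test_that("transition probabilities: identity, JC closed form, ergodic limit,
           Chapman-Kolmogorov", {
  set.seed(3)
  m <- gtrGamma(runif(6, 0.3, 4), as.numeric(phybpa:::.rdirichlet1(rep(8, 4))),
                alpha = 1)
  expect_equal(transitionProbs(m, 0), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  jc <- gtrGamma(rep(1, 6), rep(0.25, 4))
  for (t in c(0.05, 0.3, 2)) {
    P <- transitionProbs(jc, t)
    expect_equal(P[1, 1], 0.25 + 0.75 * exp(-4 * t / 3), tolerance = 1e-10)
    expect_equal(P[1, 2], 0.25 - 0.25 * exp(-4 * t / 3), tolerance = 1e-10)
  }
  Pinf <- transitionProbs(m, 500)
  for (i in 1:4)
    expect_equal(unname(Pinf[i, ]), unname(m@freqs), tolerance = 1e-8)
  # Chapman-Kolmogorov
  expect_equal(transitionProbs(m, 0.2) %*% transitionProbs(m, 0.35),
               transitionProbs(m, 0.55), tolerance = 1e-10)
  expect_error(transitionProbs(m, -0.1), "non-negative")
})

test_that("pruning equals exhaustive enumeration on 4-leaf trees", {
  set.seed(4)
  brlen <- c(a = 0.1, b = 0.25, c = 0.3, d = 0.12, x = 0.07, y = 0.05)
  tr <- tree4(brlen)
  for (rep in 1:3) {
    m <- gtrGamma(runif(6, 0.3, 4), as.numeric(phybpa:::.rdirichlet1(rep(6, 4))),
                  alpha = runif(1, 0.3, 2))
    aln <- random_alignment(4, 12, gap_prob = 0.1, missing_prob = 0.1)
    rownames(aln@seqs) <- c("a", "b", "c", "d")
    expect_equal(logLikelihood(aln, tr, m),
                 bruteforce_lnl_4leaf(aln, brlen, m), tolerance = 1e-8)
  }
})

test_that("two-taxon JC log-likelihood matches the closed form", {
  jc1 <- gtrGamma(rep(1, 6), rep(0.25, 4), alpha = 1, ncat = 1)
  tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
  same <- phyloAlignment(c(a = "A", b = "A"))
  diff <- phyloAlignment(c(a = "A", b = "G"))
  t <- 0.3
  expect_equal(logLikelihood(same, tr, jc1),
               log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))),
               tolerance = 1e-10)
  expect_equal(logLikelihood(diff, tr, jc1),
               log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3))),
               tolerance = 1e-10)
})

test_that("missing data and invariances of the likelihood", {
  set.seed(5)
  tr <- random_tree(8)
  m <- gtrGamma(runif(6, 0.3, 3), as.numeric(phybpa:::.rdirichlet1(rep(10, 4))),
                alpha = 0.9)
  aln <- random_alignment(8, 60, gap_prob = 0.05, missing_prob = 0.05)
  base <- logLikelihood(aln, tr, m)
  expect_true(is.finite(base))
  # all-missing columns contribute exactly 0
  aug <- phyloAlignment(cbind(alignmentMatrix(aln),
                              matrix("?", 8, 5,
                                     dimnames = list(taxa(aln), NULL))))
  expect_equal(logLikelihood(aug, tr, m), base, tolerance = 1e-9)
  # site order invariance
  perm <- sample(60)
  expect_equal(logLikelihood(aln[, perm], tr, m), base, tolerance = 1e-9)
  # taxon storage order invariance
  expect_equal(logLikelihood(aln[sample(8), ], tr, m), base,
               tolerance = 1e-9)
  # leaf without sequence is an error
  aln2 <- aln[1:7, ]
  expect_error(logLikelihood(aln2, tr, m), "leaf without sequence")
})

test_that("pattern compression does not change the likelihood", {
  set.seed(6)
  tr <- random_tree(5)
  m <- gtrGamma(rep(1, 6), rep(0.25, 4), alpha = 1)
  # heavy duplication: few distinct columns repeated many times
  cols <- matrix(sample(c("A", "C", "G", "T"), 5 * 4, TRUE), 5, 4)
  m2 <- cols[, sample(4, 100, TRUE)]
  rownames(m2) <- tr$tip.label
  aln <- phyloAlignment(m2)
  persite <- logLikelihood(aln, tr, m, persite = TRUE)
  expect_length(persite, 100)
  expect_equal(sum(persite), logLikelihood(aln, tr, m), tolerance = 1e-9)
})

test_that("simulation: degenerate cases, determinism, frequency recovery", {
  m <- gtrGamma(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.3, 0.2), alpha = 0.7)
  tr <- random_tree(6)
  tr0 <- tr; tr0$edge.length[] <- 0
  sim0 <- simulateAlignment(tr0, m, 50, seed = 9)
  mm <- alignmentMatrix(sim0)
  expect_true(all(apply(mm, 2, function(col) length(unique(col)) == 1)))

  s1 <- simulateAlignment(tr, m, 200, seed = 10)
  s2 <- simulateAlignment(tr, m, 200, seed = 10)
  expect_identical(alignmentMatrix(s1), alignmentMatrix(s2))

  # long branches: tip compositions converge to pi within 3 binomial SD
  tr2 <- ape::read.tree(text = "(a:50,b:50);")
  n <- 100000
  big <- simulateAlignment(tr2, m, n, seed = 11)
  bm <- alignmentMatrix(big)
  for (b in c("A", "C", "G", "T")) {
    p <- unname(m@freqs[b])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(bm["a", ] == b) - p), 3 * se + 1e-9)
  }
})

test_that("simulate-then-score: lnL is maximized near generating parameters", {
  set.seed(12)
  tr <- random_tree(8, mean_brlen = 0.1)
  m <- gtrGamma(rep(1, 6), rep(0.25, 4), alpha = 1, ncat = 4)
  aln <- simulateAlignment(tr, m, 2000, seed = 13)
  # scan a grid over a tree-length scale factor: truth should win
  scores <- sapply(c(0.25, 0.5, 1, 2, 4), function(f) {
    trf <- tr; trf$edge.length <- tr$edge.length * f
    logLikelihood(aln, trf, m)
  })
  expect_equal(which.max(scores), 3L)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  tr <- ape::rtree(6)
  tr$edge.length <- rexp(nrow(tr$edge), 10)
  m <- gtrGamma(c(1.3, 4, 0.9, 1.2, 3.5, 1), c(0.3, 0.2, 0.25, 0.25),
                alpha = 0.7)
  aln <- simulateAlignment(tr, m, 200, seed = 15)
  fit <- phangorn::pml(tr, phangorn::phyDat(alignmentMatrix(aln)),
                       model = "GTR", bf = unname(m@freqs),
                       Q = unname(m@rates), shape = 0.7, k = 4)
  expect_equal(logLikelihood(aln, tr, m), fit$logLik, tolerance = 1e-8)
})
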