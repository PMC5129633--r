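# shared fixtures built in code

library(ape)

# small random alignment over the full alphabet incl. gaps/missing
random_alignment <- function(ntaxa, nsites, gap_prob = 0, missing_prob = 0) {
  chars <- sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE)
  if (gap_prob > 0)
    chars[runif(length(chars)) < gap_prob] <- "-"
  if (missing_prob > 0)
    chars[runif(length(chars)) < missing_prob] <- "?"
  m <- matrix(chars, nrow = ntaxa,
              dimnames = list(sprintf("t%02d", seq_len(ntaxa)), NULL))
  phyloAlignment(m)
}

random_tree <- function(ntaxa, mean_brlen = 0.1) {
  tr <- ape::rphylo(ntaxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(ntaxa))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / mean_brlen)
  tr
}

# brute-force multinomial statistic: tally patterns by explicit string keys
bruteforce_T <- function(aln) {
  m <- alignmentMatrix(aln)
  m <- m[order(rownames(m)), , drop = FALSE]
  keys <- apply(m, 2, paste, collapse = "")
  tab <- table(keys)
  sum(tab * log(tab / sum(tab)))
}

# exhaustive pruning oracle: sum over all internal-node state assignments
# for the fixed 4-leaf topology ((a,b)x,(c,d)y)root
bruteforce_lnl_4leaf <- function(aln, brlen, model) {
  # brlen: named a, b, c, d, x, y
  rates <- discreteGammaRates(model@alpha, model@ncat)
  pi <- unname(model@freqs)
  lookup <- list(A = 1, C = 2, G = 3, T = 4, `-` = 1:4, `?` = 1:4, N = 1:4)
  m <- alignmentMatrix(aln)
  total <- 0
  for (j in seq_len(ncol(m))) {
    site <- 0
    for (k in seq_along(rates)) {
      P <- lapply(brlen, function(t) transitionProbs(model, t, rates[k]))
      s <- 0
      for (root in 1:4) for (x in 1:4) for (y in 1:4) {
        s <- s + pi[root] * P$x[root, x] * P$y[root, y] *
          sum(P$a[x, lookup[[m["a", j]]]]) *
          sum(P$b[x, lookup[[m["b", j]]]]) *
          sum(P$c[y, lookup[[m["c", j]]]]) *
          sum(P$d[y, lookup[[m["d", j]]]])
      }
      site <- site + s / length(rates)
    }
    total <- total + log(site)
  }
  total
}

tree4 <- function(brlen) {
  ape::read.tree(text = sprintf(
    "((a:%g,b:%g):%g,(c:%g,d:%g):%g);",
    brlen["a"], brlen["b"], brlen["x"], brlen["c"], brlen["d"], brlen["y"]))
}
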