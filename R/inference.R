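#' Prior specification
#'
#' Flat Dirichlet priors are used for exchangeabilities and base frequencies.
#' The branch-length prior is either i.i.d. exponential (the MrBayes default,
#' known to inflate tree length on partitioned data) or the compound
#' Dirichlet: a gamma prior on the total tree length with a flat Dirichlet
#' over branch-length proportions.
#'
#' @param alphaRate rate of the exponential prior on the gamma shape
#'   (default 1).
#' @param brlenPrior "exponential" or "compound_dirichlet".
#' @param brlenRate rate of the i.i.d. exponential branch-length prior
#'   (default 10, mean 0.1 per branch).
#' @param treeLengthShape,treeLengthRate gamma hyperparameters on total tree
#'   length for the compound Dirichlet prior (default shape 1, rate 1).
#' @return a \code{PriorSpec}.
#' @export
priorSpec <- function(alphaRate = 1, brlenPrior = c("exponential",
                                                    "compound_dirichlet"),
                      brlenRate = 10, treeLengthShape = 1,
                      treeLengthRate = 1) {
  brlenPrior <- match.arg(brlenPrior)
  new("PriorSpec", alphaRate = alphaRate, brlenPrior = brlenPrior,
      brlenRate = brlenRate, treeLengthShape = treeLengthShape,
      treeLengthRate = treeLengthRate)
}

#' MCMC settings
#'
#' One generation is a full sweep: Dirichlet proposals on exchangeabilities
#' and frequencies, a multiplier on the gamma shape, multipliers on a batch
#' of randomly chosen branch lengths, a whole-tree length rescaling, and
#' (optionally) one NNI topology move. Draws are recorded every
#' \code{samplefreq} generations; \code{burnin} is the fraction of recorded
#' draws discarded. With \code{nchains > 1}, Metropolis coupling uses heats
#' 1/(1 + temp * i) and one swap proposal per generation.
#'
#' @param ngen generations (default 2000).
#' @param samplefreq sampling interval in generations (default 10).
#' @param nchains number of chains (default 1).
#' @param temp heating increment (default 0.2, the MrBayes convention).
#' @param burnin burn-in fraction in [0, 1) (default 0.5).
#' @param seed RNG seed.
#' @param topologyMoves propose NNI moves (default FALSE).
#' @return an \code{MCMCSettings}.
#' @export
mcmcSettings <- function(ngen = 2000L, samplefreq = 10L, nchains = 1L,
                         temp = 0.2, burnin = 0.5, seed = 42L,
                         topologyMoves = FALSE) {
  new("MCMCSettings", ngen = as.integer(ngen),
      samplefreq = as.integer(samplefreq), nchains = as.integer(nchains),
      temp = temp, burnin = burnin, seed = as.integer(seed),
      topologyMoves = topologyMoves)
}

# log density of a Dirichlet(a) at x
.ldirichlet <- function(x, a) {
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

# branch-length log prior
.brlen_logprior <- function(b, priors) {
  if (priors@brlenPrior == "exponential") {
    sum(stats::dexp(b, rate = priors@brlenRate, log = TRUE))
  } else {
    m <- length(b)
    tl <- sum(b)
    stats::dgamma(tl, shape = priors@treeLengthShape,
                  rate = priors@treeLengthRate, log = TRUE) +
      lgamma(m) - (m - 1) * log(tl)
  }
}

# one chain state: list(r6 (simplex over 6), pi, alpha, brlen, tree, eigen,
# lnL, logpost)
.chain_logprior <- function(st, priors) {
  stats::dexp(st$alpha, rate = priors@alphaRate, log = TRUE) +
    .brlen_logprior(st$brlen, priors)
}

# random NNI rearrangement of an unrooted-style phylo; returns NULL when the
# tree has no eligible internal edge
.random_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  internal <- which(edge[, 1] > ntip & edge[, 2] > ntip)
  if (!length(internal)) return(NULL)
  e <- internal[sample.int(length(internal), 1)]
  p <- edge[e, 1]; c <- edge[e, 2]
  kids_c <- which(edge[, 1] == c)
  kids_p <- setdiff(which(edge[, 1] == p), e)
  if (!length(kids_c) || !length(kids_p)) return(NULL)
  a <- kids_c[sample.int(length(kids_c), 1)]
  b <- kids_p[sample.int(length(kids_p), 1)]
  edge[c(a, b), 2] <- edge[c(b, a), 2]
  tree$edge <- edge
  attr(tree, "order") <- NULL  # force a true re-sort after edge surgery
  ape::reorder.phylo(tree, "postorder")
}

#' Metropolis-Hastings sampler over GTR+Gamma parameters and branch lengths
#'
#' Desk-scale Bayesian sampler with a fixed or NNI-updated topology.
#' Deterministic given \code{settings@seed}. The returned
#' \code{PosteriorSample} carries the post-burn-in draws, a MrBayes-style
#' parameter trace and per-move acceptance rates.
#'
#' @param aln a \code{PhyloAlignment} (the data, e.g. one partition).
#' @param tree starting tree (ape \code{phylo} with branch lengths) covering
#'   the alignment's taxa.
#' @param priors a \code{PriorSpec}.
#' @param settings an \code{MCMCSettings}.
#' @param init_model optional starting \code{GTRGammaModel}.
#' @param ncat gamma categories (default 4).
#' @param moves character subset of c("rates", "freqs", "alpha", "brlen",
#'   "treescale"); restricting moves fixes the other parameters at their
#'   starting values.
#' @param n_brlen_moves branch multiplier moves per sweep (default
#'   min(5, n branches)).
#' @return a \code{PosteriorSample}.
#' @export
mcmcSample <- function(aln, tree, priors = priorSpec(),
                       settings = mcmcSettings(), init_model = NULL,
                       ncat = 4L,
                       moves = c("rates", "freqs", "alpha", "brlen",
                                 "treescale"),
                       n_brlen_moves = NULL) {
  stopifnot(is(aln, "PhyloAlignment"))
  if (nSites(aln) < 1) stop("empty alignment")
  missing_taxa <- setdiff(tree$tip.label, taxa(aln))
  if (length(missing_taxa))
    stop("start tree does not cover taxa: ",
         paste(missing_taxa, collapse = ", "))
  set.seed(settings@seed)
  aln <- aln[tree$tip.label, ]
  pat <- .site_patterns(aln)
  tippart_num <- as.numeric(pat$tippart)
  tord <- taxa(aln)

  if (is.null(init_model))
    init_model <- gtrGamma(rep(1, 6), .empirical_freqs(aln), alpha = 1,
                           ncat = ncat)
  nchains <- settings@nchains
  heats <- 1 / (1 + settings@temp * (seq_len(nchains) - 1))

  lnl_of <- function(st) {
    e <- st$eigen
    rates <- discreteGammaRates(st$alpha, ncat)
    .cpp_pruning_loglik(st$pt$edge, st$pt$ntip, tippart_num,
                        pat$weights, st$pi, e$A, e$Ainv, e$lambda,
                        st$brlen, rates, FALSE)[1]
  }
  make_state <- function() {
    pt <- .prep_tree(tree, tord)
    tr_post <- ape::reorder.phylo(tree, "postorder")
    r <- unname(init_model@rates); r <- r / sum(r)
    st <- list(r6 = r, pi = unname(init_model@freqs),
               alpha = init_model@alpha, brlen = pt$brlen, pt = pt,
               tree = tr_post)
    st$eigen <- gtrEigen(gtrGamma(st$r6, st$pi, st$alpha, ncat))
    st$lnL <- lnl_of(st)
    if (!is.finite(st$lnL)) stop("non-finite likelihood at start")
    st$logprior <- .chain_logprior(st, priors)
    st
  }
  chains <- lapply(seq_len(nchains), function(i) make_state())

  move_names <- c("rates", "freqs", "alpha", "brlen", "treescale",
                  "topology", "swap")
  acc <- stats::setNames(numeric(7), move_names)
  try_n <- stats::setNames(numeric(7), move_names)
  # proposal tunings, adapted toward ~30% acceptance during burn-in only
  kappa_r <- 300    # Dirichlet proposal concentrations
  kappa_pi <- 300
  lam_alpha <- 0.6  # multiplier tunings
  lam_br <- 0.8
  lam_tl <- 0.3
  nb <- length(chains[[1]]$brlen)
  if (is.null(n_brlen_moves)) n_brlen_moves <- min(5L, nb)

  mh_accept <- function(lr) is.finite(lr) && log(stats::runif(1)) < lr

  update_chain <- function(st, heat) {
    if ("rates" %in% moves) {
      try_n["rates"] <<- try_n["rates"] + 1
      prop <- as.numeric(.rdirichlet1(kappa_r * st$r6))
      if (all(prop > 1e-8)) {
        st2 <- st
        st2$r6 <- prop
        st2$eigen <- gtrEigen(gtrGamma(prop, st$pi, st$alpha, ncat))
        st2$lnL <- lnl_of(st2)
        lr <- heat * (st2$lnL - st$lnL) +
          .ldirichlet(st$r6, kappa_r * prop) -
          .ldirichlet(prop, kappa_r * st$r6)
        if (mh_accept(lr)) { st <- st2; acc["rates"] <<- acc["rates"] + 1 }
      }
    }
    if ("freqs" %in% moves) {
      try_n["freqs"] <<- try_n["freqs"] + 1
      prop <- as.numeric(.rdirichlet1(kappa_pi * st$pi))
      if (all(prop > 1e-8)) {
        st2 <- st
        st2$pi <- prop
        st2$eigen <- gtrEigen(gtrGamma(st$r6, prop, st$alpha, ncat))
        st2$lnL <- lnl_of(st2)
        lr <- heat * (st2$lnL - st$lnL) +
          .ldirichlet(st$pi, kappa_pi * prop) -
          .ldirichlet(prop, kappa_pi * st$pi)
        if (mh_accept(lr)) { st <- st2; acc["freqs"] <<- acc["freqs"] + 1 }
      }
    }
    if ("alpha" %in% moves) {
      try_n["alpha"] <<- try_n["alpha"] + 1
      mult <- exp(lam_alpha * (stats::runif(1) - 0.5))
      st2 <- st
      st2$alpha <- st$alpha * mult
      st2$lnL <- lnl_of(st2)
      st2$logprior <- .chain_logprior(st2, priors)
      lr <- heat * (st2$lnL - st$lnL) + (st2$logprior - st$logprior) +
        log(mult)
      if (mh_accept(lr)) { st <- st2; acc["alpha"] <<- acc["alpha"] + 1 }
    }
    if ("brlen" %in% moves) {
      for (k in seq_len(n_brlen_moves)) {
        try_n["brlen"] <<- try_n["brlen"] + 1
        i <- sample.int(nb, 1)
        mult <- exp(lam_br * (stats::runif(1) - 0.5))
        st2 <- st
        st2$brlen[i] <- st$brlen[i] * mult
        st2$lnL <- lnl_of(st2)
        st2$logprior <- .chain_logprior(st2, priors)
        lr <- heat * (st2$lnL - st$lnL) + (st2$logprior - st$logprior) +
          log(mult)
        if (mh_accept(lr)) { st <- st2; acc["brlen"] <<- acc["brlen"] + 1 }
      }
    }
    if ("treescale" %in% moves) {
      try_n["treescale"] <<- try_n["treescale"] + 1
      mult <- exp(lam_tl * (stats::runif(1) - 0.5))
      st2 <- st
      st2$brlen <- st$brlen * mult
      st2$lnL <- lnl_of(st2)
      st2$logprior <- .chain_logprior(st2, priors)
      lr <- heat * (st2$lnL - st$lnL) + (st2$logprior - st$logprior) +
        nb * log(mult)
      if (mh_accept(lr)) { st <- st2; acc["treescale"] <<- acc["treescale"] + 1 }
    }
    if (settings@topologyMoves) {
      try_n["topology"] <<- try_n["topology"] + 1
      cur <- st$tree               # postorder; brlen aligned to its edges
      cur$edge.length <- st$brlen
      prop_tree <- .random_nni(cur)
      if (!is.null(prop_tree)) {
        st2 <- st
        st2$tree <- prop_tree
        st2$pt <- .prep_tree(prop_tree, tord)
        st2$brlen <- st2$pt$brlen
        st2$lnL <- lnl_of(st2)
        st2$logprior <- .chain_logprior(st2, priors)
        lr <- heat * (st2$lnL - st$lnL) + (st2$logprior - st$logprior)
        if (mh_accept(lr)) { st <- st2; acc["topology"] <<- acc["topology"] + 1 }
      }
    }
    st
  }

  nsamp <- settings@ngen %/% settings@samplefreq
  trace <- vector("list", nsamp)
  draws <- vector("list", nsamp)
  si <- 0L
  adapt_every <- 100L
  adapt_until <- floor(settings@burnin * settings@ngen)
  last_acc <- acc
  last_try <- try_n
  for (gen in seq_len(settings@ngen)) {
    for (ci in seq_len(nchains))
      chains[[ci]] <- update_chain(chains[[ci]], heats[ci])
    if (gen %% adapt_every == 0L && gen <= adapt_until) {
      wa <- acc - last_acc
      wt <- try_n - last_try
      wr <- ifelse(wt > 0, wa / wt, NA_real_)
      # Dirichlet moves: larger concentration = smaller steps
      if (!is.na(wr["rates"])) {
        if (wr["rates"] < 0.15) kappa_r <- min(kappa_r * 2, 2e4)
        else if (wr["rates"] > 0.45) kappa_r <- max(kappa_r / 2, 50)
      }
      if (!is.na(wr["freqs"])) {
        if (wr["freqs"] < 0.15) kappa_pi <- min(kappa_pi * 2, 2e4)
        else if (wr["freqs"] > 0.45) kappa_pi <- max(kappa_pi / 2, 50)
      }
      # multiplier moves: smaller lambda = smaller steps
      tune_lam <- function(lam, r) {
        if (is.na(r)) lam
        else if (r < 0.15) max(lam * 0.6, 0.05)
        else if (r > 0.45) min(lam / 0.6, 3)
        else lam
      }
      lam_alpha <- tune_lam(lam_alpha, wr["alpha"])
      lam_br <- tune_lam(lam_br, wr["brlen"])
      lam_tl <- tune_lam(lam_tl, wr["treescale"])
      last_acc <- acc
      last_try <- try_n
    }
    if (nchains > 1) {
      try_n["swap"] <- try_n["swap"] + 1
      pair <- sample.int(nchains, 2)
      i <- pair[1]; j <- pair[2]
      lr <- (heats[j] - heats[i]) *
        (chains[[i]]$lnL - chains[[j]]$lnL)
      if (mh_accept(lr)) {
        tmp <- chains[[i]]; chains[[i]] <- chains[[j]]; chains[[j]] <- tmp
        acc["swap"] <- acc["swap"] + 1
      }
    }
    if (gen %% settings@samplefreq == 0L) {
      si <- si + 1L
      cold <- chains[[1]]
      r_norm <- cold$r6 / cold$r6[6]
      mdl <- gtrGamma(cold$r6, cold$pi, cold$alpha, ncat)
      tr_out <- cold$tree
      tr_out2 <- ape::reorder.phylo(tr_out, "postorder")
      tr_out2$edge.length <- cold$brlen
      draws[[si]] <- list(model = mdl, tree = tr_out2, lnL = cold$lnL)
      trace[[si]] <- c(Gen = gen, LnL = cold$lnL, TL = sum(cold$brlen),
                       r_AC = r_norm[1], r_AG = r_norm[2], r_AT = r_norm[3],
                       r_CG = r_norm[4], r_CT = r_norm[5], r_GT = r_norm[6],
                       pi_A = cold$pi[1], pi_C = cold$pi[2],
                       pi_G = cold$pi[3], pi_T = cold$pi[4],
                       alpha = cold$alpha)
    }
  }
  keep_from <- floor(nsamp * settings@burnin) + 1L
  kept <- seq.int(keep_from, nsamp)
  if (length(kept) < 10)
    stop("insufficient sample: only ", length(kept),
         " post-burn-in draws (< 10); increase ngen or reduce samplefreq")
  trace_df <- as.data.frame(do.call(rbind, trace))
  rate <- ifelse(try_n > 0, acc / try_n, NA_real_)
  new("PosteriorSample",
      models = lapply(draws[kept], `[[`, "model"),
      trees = lapply(draws[kept], `[[`, "tree"),
      lnL = vapply(draws[kept], `[[`, 0, "lnL"),
      source = "internal", trace = trace_df[kept, , drop = FALSE],
      acceptance = rate)
}

# single Dirichlet draw via gammas
.rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a, rate = 1)
  g / sum(g)
}

.empirical_freqs <- function(aln) {
  m <- alignmentMatrix(aln)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(m == b), 0)
  counts <- counts + 1
  counts / sum(counts)
}

#' @export
setMethod("show", "PosteriorSample", function(object) {
  cat("PosteriorSample:", length(object@models), "draws (",
      object@source, ")\n")
  if (length(object@acceptance))
    cat("  acceptance:",
        paste(sprintf("%s=%.2f", names(object@acceptance),
                      object@acceptance)[!is.na(object@acceptance)],
              collapse = " "), "\n")
})

#' Geweke convergence z-score
#'
#' Compares the means of the first and last segments of a trace using
#' spectral-density variance estimates from an AR fit.
#'
#' @param x numeric trace.
#' @param frac1,frac2 fractions for the leading and trailing windows.
#' @return z statistic.
#' @export
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(floor(frac1 * n))]
  x2 <- x[seq.int(n - floor(frac2 * n) + 1, n)]
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- tryCatch(stats::ar(v, aic = TRUE), error = function(e) NULL)
    if (is.null(fit) || !length(fit$ar)) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  denom <- sqrt(s0(x1) / length(x1) + s0(x2) / length(x2))
  if (denom == 0) return(0)
  (mean(x1) - mean(x2)) / denom
}

#' Maximum-likelihood point optimization under GTR+Gamma
#'
#' Coordinate ascent on a fixed topology: substitution parameters
#' (exchangeabilities, frequencies, gamma shape) and branch lengths are
#' optimized in alternating sweeps until the log-likelihood improves by less
#' than \code{tol} over a full sweep. The log-likelihood is non-decreasing
#' across sweeps.
#'
#' @param aln a \code{PhyloAlignment}.
#' @param tree ape \code{phylo} with starting branch lengths (topology
#'   fixed).
#' @param init_model optional starting \code{GTRGammaModel}.
#' @param optimize_brlens "all" (every branch), "scaler" (a single
#'   proportional rescaling of the starting branch lengths, used for
#'   per-subset fits on a shared guide tree), or "none".
#' @param fixed character subset of c("rates", "freqs", "alpha") to hold at
#'   their starting values (e.g. both + alpha for a JC-like fit).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_sweeps maximum alternating sweeps.
#' @param ncat gamma categories.
#' @return list with \code{model}, \code{tree} (optimized branch lengths),
#'   \code{lnL}, \code{lnL_path} (per-sweep values), \code{converged}.
#' @export
optimizeML <- function(aln, tree, init_model = NULL,
                       optimize_brlens = c("all", "scaler", "none"),
                       fixed = character(0), tol = 1e-6, max_sweeps = 50,
                       ncat = 4L) {
  optimize_brlens <- match.arg(optimize_brlens)
  stopifnot(is(aln, "PhyloAlignment"))
  aln <- aln[tree$tip.label, ]
  pat <- .site_patterns(aln)
  tippart_num <- as.numeric(pat$tippart)
  pt <- .prep_tree(tree, taxa(aln))
  if (is.null(init_model))
    init_model <- gtrGamma(rep(1, 6), .empirical_freqs(aln), alpha = 1,
                           ncat = ncat)
  ncat <- init_model@ncat
  state <- list(r = unname(init_model@rates),
                pi = unname(init_model@freqs),
                alpha = init_model@alpha, brlen = pt$brlen, scaler = 1)

  lnl_state <- function(st) {
    mdl <- gtrGamma(st$r, st$pi, st$alpha, ncat)
    e <- gtrEigen(mdl)
    b <- if (optimize_brlens == "scaler") pt$brlen * st$scaler else st$brlen
    .cpp_pruning_loglik(pt$edge, pt$ntip, tippart_num,
                        pat$weights, unname(mdl@freqs), e$A, e$Ainv,
                        e$lambda, b, discreteGammaRates(st$alpha, ncat),
                        FALSE)[1]
  }
  cur <- lnl_state(state)
  if (!is.finite(cur)) stop("non-finite likelihood at initial parameters")
  lnl_path <- cur

  # pack/unpack free substitution parameters
  pack <- function(st) {
    th <- numeric(0)
    if (!("rates" %in% fixed)) th <- c(th, log(st$r[1:5]))
    if (!("freqs" %in% fixed)) th <- c(th, log(st$pi[1:3] / st$pi[4]))
    if (!("alpha" %in% fixed)) th <- c(th, log(st$alpha))
    th
  }
  unpack <- function(th, st) {
    k <- 0
    if (!("rates" %in% fixed)) {
      st$r <- c(exp(th[k + 1:5]), 1); k <- k + 5
    }
    if (!("freqs" %in% fixed)) {
      w <- c(exp(th[k + 1:3]), 1); st$pi <- w / sum(w); k <- k + 3
    }
    if (!("alpha" %in% fixed)) st$alpha <- exp(th[k + 1])
    st
  }

  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    before <- cur
    th0 <- pack(state)
    if (length(th0)) {
      obj <- function(th) {
        st <- unpack(th, state)
        if (st$alpha > 1e4) st$alpha <- 1e4
        v <- lnl_state(st)
        if (!is.finite(v)) 1e12 else -v
      }
      fit <- stats::nlminb(th0, obj, control = list(rel.tol = 1e-10))
      if (-fit$objective > cur) {
        state <- unpack(fit$par, state)
        cur <- -fit$objective
      }
    }
    if (optimize_brlens == "scaler") {
      obj <- function(ls) {
        st <- state; st$scaler <- exp(ls)
        v <- lnl_state(st)
        if (!is.finite(v)) 1e12 else -v
      }
      fit <- stats::optimize(obj, c(log(1e-4), log(100)), tol = 1e-9)
      if (-fit$objective > cur) {
        state$scaler <- exp(fit$minimum)
        cur <- -fit$objective
      }
    } else if (optimize_brlens == "all") {
      for (i in seq_along(state$brlen)) {
        obj <- function(lb) {
          st <- state; st$brlen[i] <- exp(lb)
          v <- lnl_state(st)
          if (!is.finite(v)) 1e12 else -v
        }
        lo <- log(1e-9); hi <- log(50)
        fit <- stats::optimize(obj, c(lo, hi), tol = 1e-9)
        if (-fit$objective > cur) {
          state$brlen[i] <- exp(fit$minimum)
          cur <- -fit$objective
        }
      }
    }
    lnl_path <- c(lnl_path, cur)
    if (cur - before < tol) { converged <- TRUE; break }
  }

  out_tree <- ape::reorder.phylo(tree, "postorder")
  out_tree$edge.length <- if (optimize_brlens == "scaler")
    pt$brlen * state$scaler else state$brlen
  list(model = gtrGamma(state$r, state$pi, state$alpha, ncat),
       tree = out_tree, lnL = cur, lnL_path = lnl_path,
       converged = converged, scaler = state$scaler)
}

#' Bayesian Information Criterion
#'
#' @param lnL maximized log-likelihood.
#' @param K number of free parameters.
#' @param n sample size (site count), >= 1.
#' @return -2 lnL + K ln(n).
#' @export
bic <- function(lnL, K, n) {
  if (n < 1) stop("n must be >= 1")
  -2 * lnL + K * log(n)
}

#' Construct a partition scheme
#'
#' @param blocks block list (see \code{\link{buildBlocks}}).
#' @param grouping optional named list: subset name -> character vector of
#'   block names; defaults to one subset per block.
#' @return a \code{PartitionScheme}.
#' @export
partitionScheme <- function(blocks, grouping = NULL) {
  if (is.null(grouping))
    grouping <- stats::setNames(as.list(names(blocks)), names(blocks))
  subsets <- lapply(grouping, function(members) {
    unknown <- setdiff(members, names(blocks))
    if (length(unknown))
      stop("unknown blocks in grouping: ", paste(unknown, collapse = ", "))
    list(blocks = members,
         sites = sort(unlist(lapply(blocks[members], `[[`, "sites"),
                             use.names = FALSE)))
  })
  new("PartitionScheme", subsets = subsets)
}

#' @describeIn partitionScheme subset accessor
#' @param x a PartitionScheme
#' @export
setMethod("subsets", "PartitionScheme", function(x) x@subsets)

#' @export
setMethod("show", "PartitionScheme", function(object) {
  cat("PartitionScheme:", length(object@subsets), "subsets\n")
  for (nm in names(object@subsets))
    cat(sprintf("  %-20s %5d sites (%s)\n", nm,
                length(object@subsets[[nm]]$sites),
                paste(object@subsets[[nm]]$blocks, collapse = "+")))
})

#' Greedy BIC partition-scheme search
#'
#' Starts with every data block as its own subset, fits each subset by ML on
#' the shared guide tree (branch lengths proportional: guide lengths times a
#' per-subset scaler), and iteratively merges the pair of subsets whose
#' merge most improves the total BIC, stopping when no merge improves it.
#' The parameter count is 9 per subset (5 exchangeabilities + 3 frequencies
#' + 1 shape) plus the branch lengths counted once. Merge ties are broken by
#' lexicographic subset-name order, and a full merge log is returned so
#' merges can be replayed or manually overridden.
#'
#' @param blocks block list (see \code{\link{buildBlocks}}).
#' @param aln the \code{PhyloAlignment} the blocks index into.
#' @param guide_tree shared ape \code{phylo} with branch lengths.
#' @param ncat gamma categories for the per-subset fits.
#' @return list with \code{scheme} (a \code{PartitionScheme}), \code{bic},
#'   \code{start_bic} (all-separate scheme), \code{merge_log} (data.frame),
#'   \code{fits} (per-subset ML fits).
#' @export
greedySchemeSearch <- function(blocks, aln, guide_tree, ncat = 4L) {
  if (!length(blocks)) stop("need at least one block")
  all_sites <- unlist(lapply(blocks, `[[`, "sites"))
  if (anyDuplicated(all_sites)) stop("blocks overlap")
  nedges <- nrow(guide_tree$edge)
  ntot <- length(all_sites)

  fit_cache <- new.env(parent = emptyenv())
  fit_subset <- function(members) {
    key <- paste(sort(members), collapse = "|")
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    sites <- sort(unlist(lapply(blocks[members], `[[`, "sites"),
                         use.names = FALSE))
    fit <- optimizeML(aln[, sites], guide_tree,
                      optimize_brlens = "scaler", ncat = ncat)
    fit_cache[[key]] <- fit
    fit
  }
  total_bic <- function(groups) {
    lnl <- sum(vapply(groups, function(g) fit_subset(g)$lnL, 0))
    K <- 9 * length(groups) + nedges
    bic(lnl, K, ntot)
  }

  groups <- stats::setNames(as.list(names(blocks)), names(blocks))
  groups <- groups[order(names(groups))]
  cur_bic <- total_bic(groups)
  start_bic <- cur_bic
  log_rows <- list()
  step <- 0L
  while (length(groups) > 1) {
    nms <- names(groups)
    best <- NULL
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq.int(i + 1, length(nms))) {
        merged <- c(groups[[i]], groups[[j]])
        delta <- -2 * (fit_subset(merged)$lnL -
                         fit_subset(groups[[i]])$lnL -
                         fit_subset(groups[[j]])$lnL) - 9 * log(ntot)
        cand <- list(i = i, j = j, delta = delta)
        if (is.null(best) || delta < best$delta - 1e-9 ||
            (abs(delta - best$delta) <= 1e-9 &&
             paste(nms[i], nms[j]) < paste(nms[best$i], nms[best$j])))
          best <- cand
      }
    }
    if (best$delta >= 0) break
    step <- step + 1L
    newname <- paste(nms[best$i], nms[best$j], sep = "+")
    log_rows[[step]] <- data.frame(
      step = step, merged_a = nms[best$i], merged_b = nms[best$j],
      bic_before = cur_bic, bic_after = cur_bic + best$delta)
    merged_members <- c(groups[[best$i]], groups[[best$j]])
    groups <- groups[-c(best$i, best$j)]
    groups[[newname]] <- merged_members
    groups <- groups[order(names(groups))]
    cur_bic <- cur_bic + best$delta
  }
  scheme <- partitionScheme(blocks, groups)
  merge_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(0), merged_a = character(0),
               merged_b = character(0), bic_before = numeric(0),
               bic_after = numeric(0))
  list(scheme = scheme, bic = cur_bic, start_bic = start_bic,
       merge_log = merge_log,
       fits = stats::setNames(lapply(names(groups), function(nm)
         fit_subset(groups[[nm]])), names(groups)))
}
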