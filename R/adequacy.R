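#' Random taxon subsample
#'
#' Uniform subset without replacement; row order of the parent alignment is
#' preserved. Deterministic given the seed.
#'
#' @param aln a \code{PhyloAlignment}.
#' @param n subsample size (<= number of taxa).
#' @param seed optional RNG seed.
#' @return a \code{PhyloAlignment} of n taxa.
#' @export
subsampleTaxa <- function(aln, n, seed = NULL) {
  if (n > nTaxa(aln))
    stop("subsample size ", n, " exceeds taxa count ", nTaxa(aln))
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(nTaxa(aln), n))
  aln[keep, ]
}

#' Remove gap-containing columns
#'
#' Drops every column containing at least one gap character \code{-};
#' with \code{drop_missing = TRUE}, columns containing \code{?} or \code{N}
#' are dropped as well. The adequacy statistic is computed on gap-free data.
#'
#' @param aln a \code{PhyloAlignment}.
#' @param drop_missing also drop columns containing \code{?}/\code{N}.
#' @return column-subset \code{PhyloAlignment}.
#' @export
stripGapSites <- function(aln, drop_missing = FALSE) {
  m <- alignmentMatrix(aln)
  chars <- if (drop_missing) c("-", "?", "N") else "-"
  has <- colSums(matrix(m %in% chars, nrow = nrow(m))) > 0
  if (all(has)) stop("no sites remain after gap stripping")
  aln[, !has]
}

#' Multinomial likelihood test statistic
#'
#' The unconstrained multinomial log-likelihood of the observed site-pattern
#' frequencies: with pattern counts N_p over N sites,
#' T = sum_p N_p * ln(N_p / N). T <= 0, with equality iff all sites show one
#' pattern. Invariant to site order and (for a fixed taxon ordering of the
#' pattern tuples) to the labels' storage order.
#'
#' @param aln a \code{PhyloAlignment} (gap-stripped in strict use).
#' @return the statistic T.
#' @export
multinomialStatistic <- function(aln) {
  if (nSites(aln) == 0) stop("zero-length alignment")
  m <- alignmentMatrix(aln)
  m <- m[order(rownames(m)), , drop = FALSE]  # taxon order fixed
  codes <- matrix(match(m, DNA_ALPHABET), nrow = nrow(m))
  .cpp_multinomial_T(codes)
}

#' Posterior predictive assessment of one partition
#'
#' For each of \code{n_reps} posterior draws (thinned evenly across the
#' posterior sample for reproducibility), simulates a replicate alignment of
#' identical dimensions (same taxa, same site count) on the drawn tree and
#' model, computes the multinomial statistic, and locates the observed
#' statistic in the replicate distribution. The p-value is the lower-tail
#' rank with add-one correction, p = (1 + #\{T_rep <= T_obs\}) / (1 + n_reps),
#' which cannot be exactly 0 or 1.
#'
#' @param aln the observed partition alignment (gap-stripped).
#' @param posterior a \code{PosteriorSample} whose trees cover the
#'   alignment's taxa.
#' @param n_reps number of predictive replicates.
#' @param seed RNG seed.
#' @param alpha significance level for the attached decision.
#' @param tail "two" or "lower" (see \code{\link{decideAdequacy}}).
#' @param partition partition name recorded in the result.
#' @return an \code{AdequacyResult}.
#' @export
posteriorPredictive <- function(aln, posterior, n_reps = 200, seed = 1L,
                                alpha = 0.05, tail = c("two", "lower"),
                                partition = "partition") {
  tail <- match.arg(tail)
  stopifnot(is(posterior, "PosteriorSample"))
  ndraw <- length(posterior@models)
  if (ndraw == 0) stop("empty posterior")
  tr1 <- posterior@trees[[1]]
  if (is.null(tr1) || is.null(tr1$edge.length))
    stop("posterior draws lack trees with branch lengths; ",
         "supply a fixed tree (see traceToPosterior)")
  missing_taxa <- setdiff(taxa(aln), tr1$tip.label)
  if (length(missing_taxa))
    stop("posterior trees do not cover taxa: ",
         paste(missing_taxa, collapse = ", "))
  Tobs <- multinomialStatistic(aln)
  nsites <- nSites(aln)
  idx <- round(seq(1, ndraw, length.out = n_reps))
  set.seed(seed)
  ord <- sort(taxa(aln))
  Trep <- vapply(idx, function(i) {
    mdl <- posterior@models[[i]]
    trc <- ape::reorder.phylo(posterior@trees[[i]], "cladewise")
    e <- gtrEigen(mdl)
    st <- .cpp_simulate_states(trc$edge, length(trc$tip.label),
                               trc$edge.length, e$A, e$Ainv, e$lambda,
                               unname(mdl@freqs),
                               discreteGammaRates(mdl@alpha, mdl@ncat),
                               nsites)
    rownames(st) <- trc$tip.label
    .cpp_multinomial_T(st[ord, , drop = FALSE])
  }, 0)
  p <- (1 + sum(Trep <= Tobs)) / (1 + n_reps)
  res <- new("AdequacyResult", partition = partition, Tobs = Tobs,
             Trep = Trep, pValue = p, decision = "adequate",
             nReps = as.integer(n_reps),
             settings = list(alpha = alpha, tail = tail, seed = seed))
  res@decision <- decideAdequacy(res, alpha = alpha, tail = tail)
  res
}

#' Adequacy decision rule
#'
#' Two-tailed (default): the model is inadequate iff p < alpha/2 or
#' p > 1 - alpha/2 (values within the central 95\% band are adequate at
#' alpha = 0.05). Lower-tailed: inadequate iff p < alpha.
#'
#' @param result an \code{AdequacyResult} (or a bare p-value).
#' @param alpha significance level in (0, 1).
#' @param tail "two" or "lower".
#' @return "adequate" or "inadequate".
#' @export
decideAdequacy <- function(result, alpha = 0.05, tail = c("two", "lower")) {
  tail <- match.arg(tail)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- if (is(result, "AdequacyResult")) result@pValue else result
  bad <- if (tail == "two") (p < alpha / 2 || p > 1 - alpha / 2)
         else p < alpha
  if (bad) "inadequate" else "adequate"
}

#' @describeIn posteriorPredictive p-value accessor
#' @param x an AdequacyResult
#' @export
setMethod("pValue", "AdequacyResult", function(x) x@pValue)

#' @describeIn posteriorPredictive decision accessor
#' @export
setMethod("decision", "AdequacyResult", function(x) x@decision)

#' @export
setMethod("show", "AdequacyResult", function(object) {
  cat(sprintf("AdequacyResult '%s': T_obs = %.3f, p = %.4f (%d reps) -> %s\n",
              object@partition, object@Tobs, object@pValue, object@nReps,
              object@decision))
})

#' Run the full adequacy pipeline over a partition scheme
#'
#' Per partition: restrict the alignment to the partition's sites, drop taxa
#' with no data in the partition, subsample to \code{n_subsample} taxa,
#' strip gap sites, sample the posterior (internal MCMC on a
#' neighbour-joining guide tree unless a fixed \code{guide_tree} is given),
#' run the posterior predictive assessment and apply the decision rule.
#' Returns the per-partition results, a site mask excluding all sites of
#' inadequate partitions (the mask that defines the DT3 variant), and a
#' report table.
#'
#' @param aln a \code{PhyloAlignment}.
#' @param scheme a \code{PartitionScheme} over aln's coordinates.
#' @param settings \code{MCMCSettings} for the per-partition runs.
#' @param priors \code{PriorSpec} (default priors, as in adequacy-style
#'   runs).
#' @param n_subsample taxa subsampled per partition (default 30; capped at
#'   the available taxa).
#' @param n_reps predictive replicates per partition.
#' @param alpha significance level.
#' @param tail decision tail rule.
#' @param seed master seed; per-partition seeds are derived from it.
#' @param guide_tree optional fixed tree used for every partition (taxa
#'   superset); otherwise NJ on JC distances per partition.
#' @param drop_missing also strip ?/N columns before testing.
#' @return list with \code{results} (list of \code{AdequacyResult}),
#'   \code{mask} (a \code{SiteMask}, provenance "adequacy_excl"),
#'   \code{report} (data.frame), \code{excluded} (partition names).
#' @export
runAdequacyPipeline <- function(aln, scheme, settings = mcmcSettings(),
                                priors = priorSpec(), n_subsample = 30,
                                n_reps = 200, alpha = 0.05,
                                tail = c("two", "lower"), seed = 1L,
                                guide_tree = NULL, drop_missing = TRUE) {
  tail <- match.arg(tail)
  stopifnot(is(scheme, "PartitionScheme"))
  set.seed(seed)
  part_seeds <- sample.int(.Machine$integer.max %/% 2,
                           2 * length(scheme@subsets))
  results <- list()
  report <- list()
  excluded <- character(0)
  nm_all <- names(scheme@subsets)
  for (k in seq_along(nm_all)) {
    nm <- nm_all[k]
    sites <- scheme@subsets[[nm]]$sites
    sub <- aln[, sites]
    has_data <- apply(alignmentMatrix(sub), 1, function(r) any(isDataChar(r)))
    sub <- sub[has_data, ]
    nss <- min(n_subsample, nTaxa(sub))
    sub <- subsampleTaxa(sub, nss, seed = part_seeds[2 * k - 1])
    sub <- tryCatch(stripGapSites(sub, drop_missing = drop_missing),
                    error = function(e)
                      stop("partition '", nm, "': ", conditionMessage(e)))
    tr <- if (!is.null(guide_tree)) {
      ape::keep.tip(guide_tree, taxa(sub))
    } else {
      d <- ape::dist.dna(ape::as.DNAbin(alignmentMatrix(sub)), model = "JC69",
                         pairwise.deletion = TRUE)
      d[!is.finite(d)] <- max(d[is.finite(d)], 0.5)
      ape::nj(d)
    }
    tr$edge.length[tr$edge.length <= 0] <- 1e-4
    part_settings <- settings
    part_settings@seed <- part_seeds[2 * k]
    post <- tryCatch(
      mcmcSample(sub, tr, priors = priors, settings = part_settings),
      error = function(e) stop("partition '", nm, "': ",
                               conditionMessage(e)))
    res <- posteriorPredictive(sub, post, n_reps = n_reps,
                               seed = part_seeds[2 * k], alpha = alpha,
                               tail = tail, partition = nm)
    results[[nm]] <- res
    if (res@decision == "inadequate") excluded <- c(excluded, nm)
    report[[nm]] <- data.frame(
      partition = nm, n_sites = nSites(sub), n_taxa = nTaxa(sub),
      T_obs = res@Tobs, p = res@pValue, decision = res@decision)
  }
  keep <- rep(TRUE, nSites(aln))
  for (nm in excluded) keep[scheme@subsets[[nm]]$sites] <- FALSE
  list(results = results,
       mask = new("SiteMask", keep = keep, provenance = "adequacy_excl"),
       report = do.call(rbind, c(report, list(make.row.names = FALSE))),
       excluded = excluded)
}

#' Write an adequacy report
#'
#' Tab-delimited table (partition, n_sites, n_taxa, T_obs, p, decision) plus
#' an optional JSON sidecar.
#'
#' @param report the report data.frame from
#'   \code{\link{runAdequacyPipeline}}.
#' @param path output TSV path.
#' @param json also write \code{<path>.json}.
#' @export
writeAdequacyReport <- function(report, path, json = TRUE) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (json)
    jsonlite::write_json(report, paste0(path, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Calibration experiment for the posterior predictive p-value
#'
#' Repeatedly simulates data under a fixed, realistic GTR+Gamma model on a
#' fixed tree, re-fits the substitution parameters by MCMC on the known
#' tree, and runs the posterior predictive assessment, returning one
#' p-value per repeat. Under the generating model the p-values should be
#' centred (mean near 0.5); like all posterior predictive checks with a
#' data-only statistic they are somewhat conservative (less dispersed than
#' uniform), which this experiment quantifies.
#'
#' @param n_repeats number of simulated datasets.
#' @param n_taxa taxa per dataset (default 30).
#' @param n_sites sites per dataset (default 500).
#' @param n_reps predictive replicates per dataset (default 200).
#' @param ngen MCMC generations per repeat.
#' @param seed master seed.
#' @param model generating \code{GTRGammaModel} (default: a moderate
#'   transition-biased model, alpha 0.8).
#' @return numeric vector of p-values, with the generating tree attached as
#'   attribute "tree".
#' @export
calibrateAdequacy <- function(n_repeats = 200, n_taxa = 30L, n_sites = 500L,
                              n_reps = 200, ngen = 800L, seed = 1L,
                              model = NULL) {
  if (is.null(model))
    model <- gtrGamma(c(1.2, 4, 0.8, 1.1, 3.5, 1),
                      c(0.3, 0.2, 0.25, 0.25), alpha = 0.8)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / 0.03)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2, 3 * n_repeats),
                  ncol = 3)
  ps <- vapply(seq_len(n_repeats), function(i) {
    aln <- simulateAlignment(tr, model, n_sites, seed = seeds[i, 1])
    post <- mcmcSample(aln, tr,
                       settings = mcmcSettings(ngen = ngen, samplefreq = 5L,
                                               seed = seeds[i, 2]),
                       moves = c("rates", "freqs", "alpha"))
    pValue(posteriorPredictive(aln, post, n_reps = n_reps,
                               seed = seeds[i, 3]))
  }, 0)
  attr(ps, "tree") <- tr
  ps
}
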