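#' Prevalence filter
#'
#' Retains features present (count > 0) in at least `minPrevalence` of all
#' samples (inclusive threshold), preserving feature order.
#'
#' @param x a [FeatureTable-class]
#' @param minPrevalence required presence fraction in (0, 1] (default 0.2)
#' @return filtered `FeatureTable`
#' @export
prevalenceFilter <- function(x, minPrevalence = 0.2) {
  stopifnot(is(x, "FeatureTable"))
  if (minPrevalence <= 0 || minPrevalence > 1)
    stop("minPrevalence must lie in (0, 1]")
  keep <- rowMeans(asvCounts(x) > 0) >= minPrevalence
  if (!any(keep)) stop("prevalence filter removed every feature")
  x[keep, ]
}

#' Centered log-ratio transform
#'
#' Per sample, `log(p_i) - mean_j log(p_j)` on pseudocounted proportions
#' (see [relativeAbundance()]); each row of the result sums to zero.
#'
#' @param x a [FeatureTable-class] or counts matrix (features x samples)
#' @param pseudocount proportion-scale pseudocount (> 0)
#' @return samples x features real matrix
#' @export
clrTransform <- function(x, pseudocount = 1e-6) {
  lp <- log(relativeAbundance(x, pseudocount))
  sweep(lp, 1, rowMeans(lp), "-")
}

glassoObjective <- function(Theta, S, lambda) {
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(S * Theta) -
    lambda * sum(abs(Theta[upper.tri(Theta)])) * 2
}

#' Graphical lasso fit
#'
#' L1-penalized (off-diagonal only) maximum-likelihood sparse precision
#' estimation, maximizing `log det(Theta) - tr(S Theta) - lambda *
#' sum_{i != j} |Theta_ij|`, solved by block coordinate descent on the
#' covariance with coordinate-descent lasso subproblems.
#'
#' @param S symmetric positive semi-definite covariance matrix
#' @param lambda penalty (>= 0)
#' @param tol convergence threshold on the maximal parameter change per sweep
#'   (default 1e-6)
#' @param maxSweeps sweep budget (default 500); exceeding it is an error
#' @param edgeTol numerical zero for declaring an edge (default 1e-8)
#' @return list with `precision`, `adjacency` (0/1 with zero diagonal),
#'   `objective`, `sweeps`
#' @export
glassoFit <- function(S, lambda, tol = 1e-6, maxSweeps = 500, edgeTol = 1e-8) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("S must be symmetric")
  if (lambda < 0) stop("lambda must be >= 0")
  fit <- cpp_glasso(S, lambda, tol, as.integer(maxSweeps))
  if (!fit$converged)
    stop("glasso did not converge within ", maxSweeps, " sweeps")
  Theta <- fit$precision
  dimnames(Theta) <- dimnames(S)
  A <- (abs(Theta) > edgeTol) * 1
  diag(A) <- 0
  list(precision = Theta, adjacency = A,
       objective = glassoObjective(Theta, S, lambda), sweeps = fit$sweeps)
}

#' Log-spaced penalty path
#'
#' From `lambda_max` (the smallest penalty yielding an empty graph, i.e. the
#' largest absolute off-diagonal covariance) down to
#' `lambda_max * lambdaMinRatio`.
#'
#' @param S covariance matrix
#' @param nlambda path length (default 20)
#' @param lambdaMinRatio ratio of smallest to largest penalty (default 0.01)
#' @return decreasing numeric vector of penalties
#' @export
lambdaPath <- function(S, nlambda = 20, lambdaMinRatio = 0.01) {
  off <- abs(S[upper.tri(S)])
  lmax <- max(off)
  if (lmax <= 0) lmax <- 1e-4
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nlambda))
}

# StARS subsample size (the common convention).
starsSubsampleSize <- function(n) min(floor(10 * sqrt(n)), floor(0.8 * n))

#' StARS stability selection along a glasso path
#'
#' Fits the penalty path on `repNum` subsamples (without replacement, size
#' `min(floor(10*sqrt(n)), floor(0.8*n))`), measures per-penalty edge
#' instability `mean_e 2*xi_e*(1 - xi_e)` over all feature pairs (`xi_e` is
#' the subsample edge frequency), monotonizes it by a running supremum from
#' the sparse end, selects the smallest penalty (densest graph) whose
#' monotonized instability stays at or below `beta`, and refits on the full
#' data. If even the sparse path end exceeds `beta`, the densest admissible
#' end is returned with `converged = FALSE`.
#'
#' @param data samples x features real matrix (e.g. [clrTransform()] output)
#' @param nlambda,lambdaMinRatio see [lambdaPath()] (defaults 20 and 0.01)
#' @param repNum number of subsamples (default 50)
#' @param beta instability threshold (default 0.05)
#' @param seed integer seed for the subsample draws
#' @param tol,maxSweeps,edgeTol passed to the glasso core
#' @return a [NetworkModel-class]
#' @export
starsSelect <- function(data, nlambda = 20, lambdaMinRatio = 0.01,
                        repNum = 50, beta = 0.05, seed = 1,
                        tol = 1e-6, maxSweeps = 500, edgeTol = 1e-8) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < 10) stop("StARS needs at least 10 samples")
  Sfull <- stats::cov(data)
  lambdas <- lambdaPath(Sfull, nlambda, lambdaMinRatio)
  b <- starsSubsampleSize(n)
  nedge <- p * (p - 1) / 2
  freq <- matrix(0, nedge, nlambda)
  subsets <- withSeed(seed, replicate(repNum, sample.int(n, b),
                                      simplify = FALSE))
  for (idx in subsets) {
    Ssub <- stats::cov(data[idx, , drop = FALSE])
    freq <- freq + cpp_path_edges(Ssub, lambdas, tol,
                                  as.integer(maxSweeps), edgeTol)
  }
  xi <- freq / repNum
  instab <- colMeans(2 * xi * (1 - xi))
  supInstab <- cummax(instab)
  ok <- which(supInstab <= beta)
  if (length(ok)) {
    sel <- max(ok)  # smallest admissible lambda = densest stable graph
    converged <- TRUE
  } else {
    sel <- 1L
    converged <- FALSE
    warning("no penalty met the instability criterion; returning the ",
            "sparse path end")
  }
  fit <- glassoFit(Sfull, lambdas[sel], tol, maxSweeps, edgeTol)
  A <- fit$adjacency
  dimnames(A) <- list(colnames(data), colnames(data))
  methods::new("NetworkModel", adjacency = A,
               nodes = data.frame(feature_id = colnames(data) %||%
                                    paste0("F", seq_len(p))),
               selectedLambda = lambdas[sel], lambdaPath = lambdas,
               instabilityPath = supInstab, converged = converged)
}

#' Default condition subsets of the 21-day study
#'
#' Sample selectors for the three condition networks: `normal_condition`
#' (untreated, days 7 and 11), `lactose_feeding` (model and control at days
#' 5, 7, 11; test at days 5 and 7) and `treatment` (test at days 11 and 13).
#'
#' @return named list of data.frames with columns `group`, `day`
#' @export
conditionSubsets <- function() {
  list(
    normal_condition = data.frame(group = "untreated", day = c(7, 11)),
    lactose_feeding = data.frame(
      group = c(rep("model", 3), rep("control", 3), rep("test", 2)),
      day = c(5, 7, 11, 5, 7, 11, 5, 7)),
    treatment = data.frame(group = "test", day = c(11, 13)))
}

selectSamples <- function(meta, selector) {
  key <- paste(meta$group, meta$day)
  key %in% paste(selector$group, selector$day)
}

#' Condition-specific networks with node abundances
#'
#' Applies the prevalence filter over all samples (shared node set), then
#' builds one stability-selected network per condition subset (default) or a
#' single network on the pooled subset samples (`mode = "pooled"`). Node mean
#' relative abundances are computed per subset, and the `topK` nodes by
#' overall mean abundance are flagged.
#'
#' @param x a [FeatureTable-class] with `group` and `day` metadata
#' @param subsets named list of selectors, see [conditionSubsets()]
#' @param topK number of top-abundance nodes to flag (default 50)
#' @param mode `"per_subset"` (default) or `"pooled"`
#' @param minPrevalence prevalence threshold (default 0.2)
#' @param pseudocount CLR pseudocount
#' @param seed integer seed (one child seed per subset network)
#' @param ... further arguments to [starsSelect()]
#' @return list with `networks` (named list of [NetworkModel-class]) and
#'   `nodes` (node table with per-subset mean abundances and `top` flag)
#' @export
conditionNetworks <- function(x, subsets = conditionSubsets(), topK = 50,
                              mode = c("per_subset", "pooled"),
                              minPrevalence = 0.2, pseudocount = 1e-6,
                              seed = 1, ...) {
  mode <- match.arg(mode)
  stopifnot(is(x, "FeatureTable"))
  meta <- sampleData(x)
  stopifnot(all(c("group", "day") %in% names(meta)))
  filt <- prevalenceFilter(x, minPrevalence)
  sel <- lapply(subsets, selectSamples, meta = meta)
  for (nm in names(subsets)) {
    if (!any(sel[[nm]])) stop("subset '", nm, "' matches no samples")
    if (sum(sel[[nm]]) < 10)
      stop("subset '", nm, "' has fewer than 10 samples")
  }
  # relative abundance w.r.t. the full composition, then restrict to nodes
  relFull <- relativeAbundance(x, pseudocount)[, rownames(filt), drop = FALSE]
  seeds <- childSeeds(seed, length(subsets))
  networks <- list()
  if (mode == "per_subset") {
    for (k in seq_along(subsets)) {
      nm <- names(subsets)[k]
      clr <- clrTransform(filt[, sel[[nm]]], pseudocount)
      networks[[nm]] <- starsSelect(clr, seed = seeds[k], ...)
    }
  } else {
    pooled <- Reduce(`|`, sel)
    clr <- clrTransform(filt[, pooled], pseudocount)
    networks[["pooled"]] <- starsSelect(clr, seed = seeds[1], ...)
  }
  nodes <- data.frame(feature_id = rownames(filt))
  tax <- taxonomy(filt)
  for (cn in intersect(c("class", "genus", "confidence"), names(tax)))
    nodes[[cn]] <- tax[[cn]]
  for (nm in names(subsets))
    nodes[[paste0("mean_", nm)]] <-
      colMeans(relFull[sel[[nm]], , drop = FALSE])
  overall <- colMeans(relFull[Reduce(`|`, sel), , drop = FALSE])
  nodes$mean_overall <- overall
  topK <- min(topK, nrow(nodes))
  nodes$top <- rank(-overall, ties.method = "first") <= topK
  list(networks = networks, nodes = nodes)
}

#' Compare a taxon's abundance across condition subsets
#'
#' Sums the relative abundance of all features whose genus label matches
#' `taxon` (regardless of classifier confidence; confidences are reported)
#' and compares the per-sample sums between subsets with two-sided
#' Mann-Whitney tests.
#'
#' @param x a [FeatureTable-class] with taxonomy (`genus` column)
#' @param subsets named list of selectors, see [conditionSubsets()]
#' @param taxon genus label to aggregate (exact match)
#' @param pseudocount proportion-scale pseudocount
#' @return list with `summary` (per-subset n, mean, SE) and `tests`
#'   (pairwise subset comparisons with U and p)
#' @export
taxonAbundanceCompare <- function(x, subsets = conditionSubsets(), taxon,
                                  pseudocount = 1e-6) {
  tax <- taxonomy(x)
  if (!"genus" %in% names(tax)) stop("taxonomy lacks a 'genus' column")
  hit <- tax$genus == taxon
  if (!any(hit, na.rm = TRUE)) stop("taxon not found: ", taxon)
  hit[is.na(hit)] <- FALSE
  meta <- sampleData(x)
  rel <- relativeAbundance(x, pseudocount)
  perSample <- rowSums(rel[, hit, drop = FALSE])
  vals <- lapply(subsets, function(s) perSample[selectSamples(meta, s)])
  summary <- data.frame(
    subset = names(subsets),
    n = vapply(vals, length, 0L),
    mean = vapply(vals, mean, 0),
    se = vapply(vals, function(v) stats::sd(v) / sqrt(length(v)), 0),
    confidence_range = paste(
      format(range(tax$confidence[hit]), digits = 2), collapse = "-"))
  prs <- t(utils::combn(names(subsets), 2))
  tests <- do.call(rbind, lapply(seq_len(nrow(prs)), function(k) {
    mw <- mannWhitneyU(vals[[prs[k, 1]]], vals[[prs[k, 2]]])
    data.frame(subset1 = prs[k, 1], subset2 = prs[k, 2],
               U = mw$U, p = mw$p)
  }))
  list(summary = summary, tests = tests)
}
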