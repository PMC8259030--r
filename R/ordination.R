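#' Rarefy a feature table to even depth
#'
#' Samples with total counts below `depth` are dropped (with a message);
#' retained samples are subsampled without replacement to exactly `depth`
#' reads. Deterministic given `seed`.
#'
#' @param x a [FeatureTable-class]
#' @param depth target reads per sample (default 4000)
#' @param seed integer seed
#' @return a rarefied `FeatureTable`
#' @export
rarefyCounts <- function(x, depth = 4000, seed = 1) {
  stopifnot(is(x, "FeatureTable"))
  if (depth < 1) stop("depth must be >= 1")
  m <- asvCounts(x)
  tot <- colSums(m)
  drop_ <- tot < depth
  if (any(drop_))
    message("dropping ", sum(drop_), " sample(s) below depth ", depth, ": ",
            paste(utils::head(colnames(m)[drop_], 5), collapse = ", "),
            if (sum(drop_) > 5) ", ...")
  if (all(drop_)) stop("no sample reaches the rarefaction depth")
  m <- m[, !drop_, drop = FALSE]
  tot <- tot[!drop_]
  out <- withSeed(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      cj <- m[, j]
      if (tot[j] == depth) return(cj)  # exhaustive draw
      # positions 1..tot[j] partitioned by feature via cumulative boundaries
      pos <- sort.int(sample.int(tot[j], depth))
      idx <- findInterval(pos, cumsum(cj) - cj + 1)
      tabulate(idx, nbins = length(cj))
    }, numeric(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  y <- x[, !drop_]
  SummarizedExperiment::assay(y, "counts") <- out
  methods::validObject(y)
  y
}

#' Pseudocounted relative abundance profiles
#'
#' Per sample, proportions are formed, a pseudocount is added, and the result
#' is renormalized: `p_i = (c_i/sum(c) + eps) / sum_j(c_j/sum(c) + eps)`.
#' Every entry is strictly positive and each profile sums to one.
#'
#' @param x a [FeatureTable-class] or a counts matrix (features x samples)
#' @param pseudocount added to the proportion scale (default 1e-6)
#' @return samples x features matrix of profiles (rows sum to 1)
#' @export
relativeAbundance <- function(x, pseudocount = 1e-6) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (is(x, "FeatureTable")) asvCounts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  p <- sweep(m, 2, tot, "/") + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  t(p)
}

kld <- function(x, y) sum(x * log(x / y))

#' Square-root Jensen-Shannon divergence between two profiles
#'
#' `D = sqrt(KLD(p, m)/2 + KLD(q, m)/2)` with `m = (p + q)/2` and the
#' Kullback-Leibler divergence in natural log, so `D` is a metric bounded by
#' `sqrt(log(2))`.
#'
#' @param p,q probability vectors of equal length (entries > 0 after
#'   pseudocounting; exact zeros are tolerated via the 0*log(0) = 0 limit)
#' @return the sqrt-JSD distance
#' @examples
#' jsdDistance(c(0.5, 0.5), c(0.25, 0.75))
#' @export
jsdDistance <- function(p, q) {
  if (length(p) != length(q)) stop("profiles differ in length")
  m <- (p + q) / 2
  term <- function(x) {
    i <- x > 0
    sum(x[i] * log(x[i] / m[i]))
  }
  d2 <- (term(p) + term(q)) / 2
  sqrt(max(d2, 0))
}

#' Pairwise sqrt-JSD distance matrix
#'
#' @param profiles samples x features matrix of probability profiles (rows sum
#'   to 1), as from [relativeAbundance()]
#' @return symmetric labelled distance matrix with zero diagonal
#' @export
pairwiseJsd <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least two profiles")
  # JSD(x, y) = H(m) - (H(x) + H(y))/2 with H the Shannon entropy (nats)
  xlogx <- function(M) {
    Z <- M * log(M)
    Z[M == 0] <- 0
    rowSums(Z)
  }
  self <- xlogx(profiles)
  D <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    M <- (profiles[j, , drop = FALSE] +
            matrix(profiles[i, ], length(j), ncol(profiles), byrow = TRUE)) / 2
    jsd2 <- (self[i] + self[j]) / 2 - xlogx(M)
    D[i, j] <- D[j, i] <- sqrt(pmax(jsd2, 0))
  }
  D
}

#' Classical principal coordinate analysis
#'
#' Gower double centering `B = -1/2 * J D^2 J` followed by an
#' eigendecomposition. Coordinates are returned for the first `k` positive
#' eigenvalues as eigenvector * sqrt(eigenvalue); negative eigenvalues are
#' reported in the spectrum, not corrected. Axis signs are fixed
#' deterministically: each column's largest-magnitude loading is made
#' positive.
#'
#' @param D symmetric distance matrix with zero diagonal
#' @param k number of axes to retain (1 <= k < n; silently capped at the
#'   number of positive eigenvalues)
#' @return an [Ordination-class]
#' @export
classicalPcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric square matrix")
  if (any(diag(D) != 0) || any(D < 0))
    stop("D must have a zero diagonal and non-negative entries")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tolPos <- max(abs(ev)) * 1e-9
  pos <- which(ev > tolPos)
  kk <- min(k, length(pos))
  if (kk == 0) {
    coords <- matrix(0, n, k, dimnames = list(rownames(D), paste0("PCo", 1:k)))
    return(methods::new("Ordination", coordinates = coords,
                        eigenvalues = ev, proportionExplained = rep(0, k)))
  }
  V <- e$vectors[, pos[seq_len(kk)], drop = FALSE]
  L <- ev[pos[seq_len(kk)]]
  for (j in seq_len(kk)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- sweep(V, 2, sqrt(L), "*")
  dimnames(coords) <- list(rownames(D), paste0("PCo", seq_len(kk)))
  methods::new("Ordination", coordinates = coords, eigenvalues = ev,
               proportionExplained = L / sum(ev[ev > 0]))
}

#' Loess trajectory of an ordination axis per group
#'
#' Locally weighted polynomial regression (degree 2, tricube weights — the
#' `stats::loess` defaults) of an axis coordinate against collection day,
#' fitted separately per group, with a 95% pointwise band
#' `fit +/- 1.96 * SE`. Groups with fewer than 5 samples are skipped with a
#' warning.
#'
#' @param values numeric axis coordinate per sample (e.g. PCo1)
#' @param day numeric collection day per sample
#' @param group group label per sample
#' @param span Loess span in (0, 1] (default 0.75)
#' @param newDays evaluation grid (default: the observed days of each group)
#' @return data.frame `(group, day, fit, se, lower, upper)`
#' @export
loessTrajectory <- function(values, day, group, span = 0.75, newDays = NULL) {
  stopifnot(length(values) == length(day), length(day) == length(group))
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  out <- list()
  for (g in unique(group)) {
    i <- group == g
    if (sum(i) < 5) {
      warning("group '", g, "' has fewer than 5 samples; skipped")
      next
    }
    fit <- suppressWarnings(
      stats::loess(y ~ x, data = data.frame(x = day[i], y = values[i]),
                   span = span, degree = 2,
                   control = stats::loess.control(surface = "direct")))
    grid <- if (is.null(newDays)) sort(unique(day[i])) else sort(newDays)
    pr <- suppressWarnings(stats::predict(fit, newdata = data.frame(x = grid),
                                          se = TRUE))
    se <- ifelse(is.finite(pr$se.fit), pr$se.fit, 0)
    out[[g]] <- data.frame(group = g, day = grid, fit = as.numeric(pr$fit),
                           se = se,
                           lower = as.numeric(pr$fit) - 1.96 * se,
                           upper = as.numeric(pr$fit) + 1.96 * se)
  }
  if (!length(out)) stop("no group had enough samples for a trajectory")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided Mann-Whitney U test with mid-rank ties
#'
#' Exact null by complete enumeration of rank assignments when both sides have
#' at most 8 observations (conditional on the observed tie pattern); normal
#' approximation with tie-corrected variance otherwise (no continuity
#' correction). Two-sided p-values measure deviations of U from its null mean
#' `n1*n2/2`.
#'
#' @param x,y numeric samples
#' @return list with `U` (statistic for `x`) and `p`
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(N, n1)
    Ustar <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Ustar - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    p <- if (sig2 <= 0) 1 else
      min(1, 2 * stats::pnorm(-abs(U - mu) / sqrt(sig2)))
  }
  list(U = unname(U), p = unname(p))
}

#' Per-day group comparisons with BH correction
#'
#' For every (day, group-pair) cell with at least 2 samples per side, a
#' two-sided Mann-Whitney test ([mannWhitneyU()]) of `values`;
#' Benjamini-Hochberg correction is applied jointly across all tested cells.
#' Cells that cannot be tested are recorded with `NA` and excluded from the
#' BH family.
#'
#' @param values numeric per-sample response (e.g. PCo1)
#' @param metadata data.frame with columns `group` and `day`, one row per
#'   sample, aligned with `values`
#' @param pairs optional 2-column matrix/data.frame of group pairs (default:
#'   all unordered pairs of observed groups)
#' @return data.frame `(day, group1, group2, n1, n2, U, p, q)`
#' @export
perDayGroupTests <- function(values, metadata, pairs = NULL) {
  stopifnot(all(c("group", "day") %in% names(metadata)),
            length(values) == nrow(metadata))
  groups <- unique(as.character(metadata$group))
  if (is.null(pairs)) {
    if (length(groups) < 2) stop("need at least two groups")
    pairs <- t(utils::combn(groups, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- list()
  for (d in sort(unique(metadata$day))) {
    for (k in seq_len(nrow(pairs))) {
      i1 <- metadata$day == d & metadata$group == pairs[k, 1]
      i2 <- metadata$day == d & metadata$group == pairs[k, 2]
      n1 <- sum(i1); n2 <- sum(i2)
      if (n1 >= 2 && n2 >= 2) {
        mw <- mannWhitneyU(values[i1], values[i2])
        rows[[length(rows) + 1L]] <- data.frame(
          day = d, group1 = pairs[k, 1], group2 = pairs[k, 2],
          n1 = n1, n2 = n2, U = mw$U, p = mw$p)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          day = d, group1 = pairs[k, 1], group2 = pairs[k, 2],
          n1 = n1, n2 = n2, U = NA_real_, p = NA_real_)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  tested <- !is.na(res$p)
  res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res
}
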