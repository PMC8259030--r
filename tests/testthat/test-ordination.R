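test_that("rarefaction subsamples without replacement to exact depth", {
  m <- matrix(c(8000, 0, 3000, 2000, 2500, 1500, 500, 100), nrow = 2,
              dimnames = list(c("ASV1", "ASV2"), paste0("S", 1:4)))
  ft <- tinyFeatureTable(m)
  expect_message(rar <- rarefyCounts(ft, depth = 4000, seed = 1), "S4")
  cm <- asvCounts(rar)
  expect_equal(unname(colSums(cm)), rep(4000, ncol(cm)))
  expect_equal(unname(cm[, "S1"]), c(4000, 0))  # single-feature degenerate
  # exhaustive draw: a sample at exactly the target depth is unchanged
  m2 <- matrix(c(2500, 1500, 3000, 3000), nrow = 2,
               dimnames = list(c("ASV1", "ASV2"), c("S1", "S2")))
  rar2 <- rarefyCounts(tinyFeatureTable(m2), depth = 4000, seed = 5)
  expect_equal(unname(asvCounts(rar2)[, "S1"]), c(2500, 1500))
  expect_identical(asvCounts(rarefyCounts(ft, 4000, seed = 9)),
                   asvCounts(rarefyCounts(ft, 4000, seed = 9)))
  expect_error(rarefyCounts(ft, depth = 0), "depth")
})

test_that("rarefied feature means follow the hypergeometric expectation", {
  counts <- c(1200, 700, 80, 15, 5)
  m <- matrix(counts, ncol = 1, dimnames = list(paste0("ASV", 1:5), "S1"))
  md <- data.frame(row.names = "S1", group = "untreated", day = 1,
                   mouse = "m1", cage = "c1")
  ft <- FeatureTable(m, md)
  depth <- 500
  draws <- sapply(1:300, function(s)
    asvCounts(rarefyCounts(ft, depth, seed = s))[, 1])
  expect_true(all(colSums(draws) == depth))
  expmean <- depth * counts / sum(counts)
  mcse <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - expmean) <= 3 * pmax(mcse, 1e-12)))
})

test_that("pseudocounted profiles are positive, normalized and symmetric", {
  m <- matrix(c(1, 1, 1, 1), ncol = 1,
              dimnames = list(paste0("ASV", 1:4), "S1"))
  p <- relativeAbundance(m)
  expect_equal(unname(p[1, ]), rep(0.25, 4))
  m2 <- matrix(c(4000, 0), ncol = 1, dimnames = list(c("A", "B"), "S1"))
  p2 <- relativeAbundance(m2)
  expect_true(all(p2 > 0))
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  set.seed(1)
  m3 <- matrix(rpois(60, 30), nrow = 6,
               dimnames = list(paste0("A", 1:6), paste0("S", 1:10)))
  expect_true(all(abs(rowSums(relativeAbundance(m3)) - 1) < 1e-12))
  m3[, 3] <- 0
  expect_error(relativeAbundance(m3), "S3")
  expect_error(relativeAbundance(m3[, 1:2], pseudocount = 0), "pseudocount")
})

test_that("sqrt-JSD matches its definition, attains its bound, and is a metric", {
  expect_equal(jsdDistance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsdDistance(c(1, 0), c(0, 1)), sqrt(log(2)))
  # brute-force term-by-term oracle on a worked pair and on random pairs
  expect_equal(jsdDistance(c(0.5, 0.5), c(0.25, 0.75)),
               refSqrtJsd(c(0.5, 0.5), c(0.25, 0.75)), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    p <- randomProfile(12); q <- randomProfile(12)
    expect_equal(jsdDistance(p, q), refSqrtJsd(p, q), tolerance = 1e-12)
  }
  expect_error(jsdDistance(c(0.5, 0.5), c(1, 0, 0)), "length")
  # metric properties on random triples
  set.seed(2)
  for (i in 1:50) {
    x <- randomProfile(15); y <- randomProfile(15); z <- randomProfile(15)
    dxy <- jsdDistance(x, y); dyz <- jsdDistance(y, z); dxz <- jsdDistance(x, z)
    expect_equal(dxy, jsdDistance(y, x))
    expect_lte(dxz, dxy + dyz + 1e-12)
    expect_true(dxy >= 0 && dxy <= sqrt(log(2)) + 1e-9)
    expect_lt(jsdDistance(x, x), 1e-12)
  }
})

test_that("the pairwise distance matrix equals element-wise recomputation", {
  set.seed(4)
  P <- t(replicate(6, randomProfile(10)))
  rownames(P) <- paste0("S", 1:6)
  D <- pairwiseJsd(P)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], refSqrtJsd(P[i, ], P[j, ]), tolerance = 1e-12)
  # permutation equivariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(pairwiseJsd(P[perm, ]), D[perm, perm])
  expect_equal(max(pairwiseJsd(P[c(2, 2), ])), 0)
})

test_that("classical PCoA reproduces hand-computed and Euclidean embeddings", {
  # three colinear points: d(1,2) = d(2,3) = 1, d(1,3) = 2
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  ord <- classicalPcoa(D, k = 2)
  co <- ordCoordinates(ord)
  expect_equal(abs(co[, 1]), c(S1 = 1, S2 = 0, S3 = 1), tolerance = 1e-9)
  expect_equal(sort(co[, 1]), c(S1 = -1, S2 = 0, S3 = 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(eigenvalues(ord)[1], 2, tolerance = 1e-9)
  expect_lt(max(abs(eigenvalues(ord)[-1])), 1e-9)
  # Euclidean configuration is reconstructed exactly
  set.seed(8)
  X <- matrix(rnorm(6 * 3), 6, 3)
  DX <- as.matrix(dist(X)); dimnames(DX) <- list(paste0("P", 1:6), paste0("P", 1:6))
  orX <- classicalPcoa(DX, k = 5)
  rec <- as.matrix(dist(ordCoordinates(orX)))
  expect_lt(max(abs(rec - DX)), 1e-8)
  # spectral identity: sum of eigenvalues equals trace of the centred matrix
  n <- 6; J <- diag(n) - 1 / n
  B <- -0.5 * J %*% DX^2 %*% J
  expect_equal(sum(eigenvalues(orX)), sum(diag(B)), tolerance = 1e-9)
  # degenerate: identical samples collapse to the origin
  D0 <- matrix(0, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  expect_true(all(ordCoordinates(classicalPcoa(D0, 2)) == 0))
  bad <- DX; bad[1, 2] <- bad[1, 2] + 1
  expect_error(classicalPcoa(bad, 2), "symmetric")
})

test_that("PCoA agrees with the reference classical-scaling implementations", {
  set.seed(13)
  P <- t(replicate(9, randomProfile(20)))
  rownames(P) <- paste0("S", 1:9)
  D <- pairwiseJsd(P)
  ord <- classicalPcoa(D, k = 3)
  ref <- stats::cmdscale(D, k = 3, eig = TRUE)
  for (j in 1:3)
    expect_equal(abs(ordCoordinates(ord)[, j]), abs(ref$points[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(eigenvalues(ord)[1:3], ref$eig[1:3], tolerance = 1e-8)
  ape_ord <- ape::pcoa(as.dist(D))
  expect_equal(eigenvalues(ord)[1:3], ape_ord$values$Eigenvalues[1:3],
               tolerance = 1e-8)
})

test_that("Loess trajectories reproduce degenerate and linear references", {
  day <- rep(seq(1, 21, 2), each = 3)
  grp <- rep("untreated", length(day))
  const <- loessTrajectory(rep(2.5, length(day)), day, grp, span = 0.75)
  expect_equal(const$fit, rep(2.5, 11), tolerance = 1e-9)
  expect_lt(max(const$upper - const$lower), 1e-8)
  set.seed(5)
  y <- 0.3 * day - 1
  lin <- loessTrajectory(y, day, grp, span = 1)
  expect_equal(lin$fit, 0.3 * sort(unique(day)) - 1, tolerance = 1e-6)
  # insensitive to sample order
  o <- sample(length(day))
  lin2 <- loessTrajectory(y[o], day[o], grp[o], span = 1)
  expect_equal(lin$fit, lin2$fit, tolerance = 1e-9)
  expect_warning(
    loessTrajectory(c(y, 1), c(day, 3), c(grp, "tiny"), span = 1), "tiny")
})

test_that("Mann-Whitney matches exact enumeration and the reference implementation", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)   # 2 / choose(6, 3)
  expect_equal(mannWhitneyU(c(5, 5, 5), c(5, 5, 5))$p, 1)
  set.seed(21)
  # exact branch against wilcox.test's exact p on tie-free data
  for (i in 1:10) {
    x <- rnorm(sample(3:7, 1)); y <- rnorm(sample(3:7, 1))
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    mine <- mannWhitneyU(x, y)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # normal-approximation branch (tie-corrected, uncorrected for continuity)
  for (i in 1:5) {
    x <- round(rnorm(12), 1); y <- round(rnorm(15), 1)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mannWhitneyU(x, y)$p, ref$p.value, tolerance = 1e-12)
  }
  # disjoint 5 vs 5: exact two-sided 2 / choose(10, 5)
  expect_equal(mannWhitneyU(1:5, 6:10)$p, 2 / choose(10, 5))
})

test_that("per-day group tests form one BH family over testable cells", {
  md <- data.frame(
    group = rep(c("untreated", "model"), times = c(12, 12)),
    day = rep(c(1, 3, 5), each = 4, times = 2))
  set.seed(3)
  v <- rnorm(24)
  v[md$group == "model" & md$day == 5] <- v[md$group == "model" & md$day == 5] + 10
  res <- perDayGroupTests(v, md)
  expect_equal(nrow(res), 3)
  # hand step-up BH as the oracle for the joint family
  p <- res$p
  n <- length(p); o <- order(p, decreasing = TRUE)
  qexp <- rev(cummin(rev(sort(p) * n / seq_len(n))))[rank(p)]
  expect_equal(res$q, pmin(qexp, 1), tolerance = 1e-12)
  # untestable cells are recorded as missing and excluded from the family
  md2 <- rbind(md, data.frame(group = "test", day = 1))
  res2 <- perDayGroupTests(c(v, 1), md2)
  expect_true(all(is.na(res2$q[res2$n1 < 2 | res2$n2 < 2])))
  expect_equal(sum(!is.na(res2$p)), 3)
})
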