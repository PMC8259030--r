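test_that("the prevalence filter applies an inclusive threshold", {
  set.seed(1)
  m <- matrix(rpois(5 * 10, 20), nrow = 5,
              dimnames = list(paste0("ASV", 1:5), paste0("S", 1:10)))
  m[2, ] <- 0; m[2, 4] <- 7              # 1/10 samples
  m[3, ] <- 0; m[3, c(2, 9)] <- c(3, 5)  # exactly 2/10 samples
  ft <- tinyFeatureTable(m)
  kept <- rownames(prevalenceFilter(ft, 0.2))
  expect_true("ASV1" %in% kept)          # present everywhere
  expect_false("ASV2" %in% kept)
  expect_true("ASV3" %in% kept)          # boundary 2/10 at 0.2 is retained
  mz <- m; mz[cbind(1:5, 1:5)] <- 0      # every feature absent somewhere
  expect_error(prevalenceFilter(tinyFeatureTable(mz), 1), "every feature")
  expect_error(prevalenceFilter(ft, 0), "minPrevalence")
})

test_that("the CLR transform centres log-proportions per sample", {
  m <- matrix(c(5, 5, 5, 5), ncol = 1, dimnames = list(paste0("A", 1:4), "S1"))
  expect_equal(unname(clrTransform(m)[1, ]), rep(0, 4))
  m2 <- matrix(c(3, 1), ncol = 1, dimnames = list(c("A", "B"), "S1"))
  expect_equal(unname(clrTransform(m2, pseudocount = 1e-12)[1, ]),
               c(log(3) / 2, -log(3) / 2), tolerance = 1e-9)
  set.seed(2)
  m3 <- matrix(rpois(80, 25) + 1, nrow = 8,
               dimnames = list(paste0("A", 1:8), paste0("S", 1:10)))
  expect_lt(max(abs(rowSums(clrTransform(m3)))), 1e-9)
})

test_that("glasso reproduces closed-form degenerate cases", {
  S <- diag(c(2, 3, 4))
  f <- glassoFit(S, 0.1)
  expect_equal(f$precision, diag(c(0.5, 1 / 3, 0.25)), tolerance = 1e-9)
  expect_equal(sum(f$adjacency), 0)
  # full shrinkage at lambda >= max off-diagonal
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3); X[, 2] <- X[, 2] + X[, 1]
  S2 <- cov(X)
  lam <- max(abs(S2[upper.tri(S2)]))
  expect_equal(sum(glassoFit(S2, lam + 1e-9)$adjacency), 0)
  expect_gt(sum(glassoFit(S2, lam / 10)$adjacency), 0)
  expect_error(glassoFit(S2, -1), "lambda")
  expect_error(glassoFit(matrix(c(1, 2, 0, 1), 2, 2), 0.1), "symmetric")
  expect_error(glassoFit(S2, 0.01, maxSweeps = 0), "converge")
})

test_that("glasso matches the brute-force penalized-likelihood oracle on small problems", {
  set.seed(7)
  for (p in 2:4) {
    X <- matrix(rnorm(60 * p), 60, p)
    X[, 1] <- X[, 1] + 0.8 * X[, p]
    S <- cov(X)
    for (lam in c(0.03, 0.15)) {
      fit <- glassoFit(S, lam, tol = 1e-9)
      oracle <- bruteForceGlasso(S, lam, iters = 100)
      expect_lt(abs(fit$objective - oracle$objective), 1e-6)
      ev <- eigen(fit$precision, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("edge counts decrease monotonically along the penalty path", {
  set.seed(8)
  g <- simulatePrecisionGraphData(12, 80, "band", seed = 3)
  S <- cov(g$data)
  lambdas <- lambdaPath(S, nlambda = 12, lambdaMinRatio = 0.02)
  expect_equal(length(lambdas), 12)
  expect_true(all(diff(lambdas) < 0))
  ecount <- sapply(lambdas, function(l) sum(glassoFit(S, l)$adjacency) / 2)
  expect_equal(ecount[1], 0)   # lambda_max gives the empty graph
  expect_true(all(diff(ecount) >= 0))
})

test_that("StARS instability is zero for duplicated rows and bounded on real paths", {
  row <- rnorm(8)
  X <- matrix(rep(row, each = 40), 40, 8)
  colnames(X) <- paste0("F", 1:8)
  net <- starsSelect(X, nlambda = 8, repNum = 10, seed = 4)
  expect_true(all(instabilityPath(net) == 0))
  g <- simulatePrecisionGraphData(15, 60, "chain", seed = 9)
  net2 <- starsSelect(g$data, nlambda = 10, repNum = 10, seed = 2)
  ip <- instabilityPath(net2)
  expect_true(all(ip >= 0 & ip <= 0.5))
  expect_true(all(diff(ip) >= 0))  # running supremum along decreasing lambda
  net3 <- starsSelect(g$data, nlambda = 10, repNum = 10, seed = 2)
  expect_equal(adjacency(net2), adjacency(net3))
  expect_error(starsSelect(g$data[1:5, ]), "10 samples")
})

test_that("StARS recovers a chain precision graph", {
  g <- simulatePrecisionGraphData(20, 150, "chain", seed = 5)
  net <- starsSelect(g$data, nlambda = 15, repNum = 10, seed = 5)
  expect_gte(edgeF1(adjacency(net), g$adjacency), 0.6)
})

test_that("condition networks share nodes, report abundances and flag top taxa", {
  cfg <- studyConfig(nMicePerGroup = 10, nFeatures = 60, depthMean = 3000,
                     seed = 30)
  ft <- simulateStudy(cfg)
  nets <- conditionNetworks(ft, topK = 15, repNum = 6, nlambda = 8)
  expect_named(nets$networks,
               c("normal_condition", "lactose_feeding", "treatment"))
  expect_equal(sum(nets$nodes$top), 15)
  # generator ground truth: the Bacteroides-like block is less abundant
  # under lactose feeding than under normal conditions
  blk <- nets$nodes$genus == "Bacteroides"
  expect_lt(sum(nets$nodes$mean_lactose_feeding[blk]),
            sum(nets$nodes$mean_normal_condition[blk]))
  # all nodes flagged when topK covers them
  netsAll <- conditionNetworks(ft, topK = 1e6, repNum = 6, nlambda = 8)
  expect_true(all(netsAll$nodes$top))
  # a selector matching nothing errors with the subset name
  bad <- conditionSubsets()
  bad$treatment <- data.frame(group = "test", day = 20)
  expect_error(conditionNetworks(ft, subsets = bad), "treatment")
  # pooled mode returns a single network on the union of subsets
  pooled <- conditionNetworks(ft, mode = "pooled", repNum = 6, nlambda = 8)
  expect_named(pooled$networks, "pooled")
})

test_that("subset node abundances equal the sample proportions for identical samples", {
  m <- matrix(rep(c(60, 30, 10), 12), nrow = 3,
              dimnames = list(paste0("ASV", 1:3), paste0("S", 1:12)))
  md <- data.frame(row.names = colnames(m),
                   group = "untreated", day = rep(c(7, 11), 6),
                   mouse = paste0("m", 1:12), cage = "c1")
  ft <- FeatureTable(m, md)
  sub <- list(normal_condition = data.frame(group = "untreated",
                                            day = c(7, 11)))
  nets <- conditionNetworks(ft, subsets = sub, topK = 3, repNum = 5,
                            nlambda = 5)
  expect_equal(nets$nodes$mean_normal_condition, c(0.6, 0.3, 0.1),
               tolerance = 1e-4)
})

test_that("taxon comparisons aggregate by genus and use exact small-sample tests", {
  cfg <- studyConfig(nMicePerGroup = 10, nFeatures = 60, depthMean = 3000,
                     seed = 31)
  ft <- simulateStudy(cfg)
  res <- taxonAbundanceCompare(ft, taxon = "Bacteroides")
  s <- res$summary
  expect_lt(s$mean[s$subset == "lactose_feeding"],
            s$mean[s$subset == "normal_condition"])
  expect_true(all(res$tests$p >= 0 & res$tests$p <= 1))
  expect_error(taxonAbundanceCompare(ft, taxon = "Vibrio"), "not found")
  # identical subsets give p = 1; disjoint 5 vs 5 gives 2 / choose(10, 5)
  m <- matrix(rep(c(50, 50), 10), nrow = 2,
              dimnames = list(c("A", "B"), paste0("S", 1:10)))
  m[1, 6:10] <- 90  # well-separated second subset
  md <- data.frame(row.names = colnames(m), group = "untreated",
                   day = rep(c(7, 11), each = 5),
                   mouse = paste0("m", 1:10), cage = "c1")
  tx <- data.frame(row.names = c("A", "B"), genus = c("Bacteroides", "Other"),
                   class = c("Bacteroidia", "Bacilli"), confidence = 0.9)
  ft2 <- FeatureTable(m, md, tx)
  subs <- list(a = data.frame(group = "untreated", day = 7),
               b = data.frame(group = "untreated", day = 11))
  cmp <- taxonAbundanceCompare(ft2, subs, "Bacteroides")
  expect_equal(cmp$tests$p, 2 / choose(10, 5))
  subsEq <- list(a = data.frame(group = "untreated", day = c(7, 11)),
                 b = data.frame(group = "untreated", day = c(7, 11)))
  cmpEq <- taxonAbundanceCompare(ft2, subsEq, "Bacteroides")
  expect_equal(cmpEq$tests$p, 1)
})
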