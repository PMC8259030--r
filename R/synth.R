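#' Configuration for a synthetic 21-day microbiome study
#'
#' Emulates the post-denoising product of the 4-group murine design: four
#' phases (I days 1-3 normal care, II days 4-9 lactose challenge, III days
#' 10-15 bacterial treatment, IV days 16-21 restoration), groups untreated /
#' model / control / test with `nMicePerGroup` mice each. Mice are sampled on
#' alternate days in two interleaved 5-mouse cohorts (cohort A on days
#' 1,5,9,13,17,21; cohort B on days 3,7,11,15,19), giving 55 samples per
#' group of 10 mice — matching the study's per-group totals of 53-59 once
#' low-depth samples drop out at rarefaction.
#'
#' The latent structure: per-feature log-normal baseline; a shared temporal
#' drift that ramps linearly over days 3-11 and loads on the Bacteroides-like
#' block (35 of the 50 most abundant features are tagged class Bacteroidia);
#' a lactose effect (suppression of the same block by
#' `bacteroidesSuppression` log-units, boost of the Lactobacillus-like
#' feature by `lactobacillusBoost`) applied to model/control/test during
#' phase II and to model/control during phase III; the test group reverts to
#' the shared trend in phase III. Counts are Dirichlet-multinomial.
#'
#' @param nMicePerGroup mice per group (default 10)
#' @param groups group labels (default the four study arms)
#' @param nFeatures number of ASVs (default 300)
#' @param depthMean mean sequencing depth (default 8000, log-normal across
#'   samples with `depthSdlog`)
#' @param depthSdlog log-sd of depth (default 0.35)
#' @param bacteroidesSuppression lactose effect on the Bacteroides-like block
#'   (log-fold, default -0.5)
#' @param lactobacillusBoost lactose effect on the Lactobacillus-like feature
#'   (log-fold, default +0.7)
#' @param driftMagnitude full-ramp magnitude of the shared drift (log-fold on
#'   the Bacteroides-like block, default 0.8)
#' @param baselineSdlog log-sd of the feature baseline (default 2.2)
#' @param mouseSd per-mouse, per-feature baseline heterogeneity (log-sd,
#'   default 0.15)
#' @param cageEffectSd cage random-intercept log-sd (default 0, i.e. off)
#' @param concentration Dirichlet concentration (overdispersion; default 300)
#' @param sampling `"alternating"` cohorts (default) or `"daily"` (every
#'   mouse on every day in `samplingDays`)
#' @param samplingDays days used when `sampling = "daily"` (default odd days)
#' @param seed integer seed; the whole study is deterministic given it
#' @return list of class `StudyConfig`
#' @export
studyConfig <- function(nMicePerGroup = 10,
                        groups = c("untreated", "model", "control", "test"),
                        nFeatures = 300, depthMean = 8000, depthSdlog = 0.35,
                        bacteroidesSuppression = -0.5,
                        lactobacillusBoost = 0.7,
                        driftMagnitude = 0.8, baselineSdlog = 1.5,
                        mouseSd = 0.15, cageEffectSd = 0,
                        concentration = 300,
                        sampling = c("alternating", "daily"),
                        samplingDays = seq(1, 21, by = 2), seed = 1) {
  sampling <- match.arg(sampling)
  stopifnot(nMicePerGroup >= 1, nFeatures >= 10, depthMean > 0,
            concentration > 0)
  structure(list(
    nMicePerGroup = nMicePerGroup, groups = groups, nFeatures = nFeatures,
    depthMean = depthMean, depthSdlog = depthSdlog,
    bacteroidesSuppression = bacteroidesSuppression,
    lactobacillusBoost = lactobacillusBoost,
    driftMagnitude = driftMagnitude, baselineSdlog = baselineSdlog,
    mouseSd = mouseSd, cageEffectSd = cageEffectSd,
    concentration = concentration, sampling = sampling,
    samplingDays = samplingDays, seed = seed,
    phases = list(I = 1:3, II = 4:9, III = 10:15, IV = 16:21)),
    class = "StudyConfig")
}

#' Study phase of a day
#' @param day numeric day in 1..21
#' @return character phase label ("I".."IV")
#' @export
phaseOfDay <- function(day) {
  cut(day, breaks = c(0, 3, 9, 15, 21), labels = c("I", "II", "III", "IV"))
}

# Linear ramp of the shared drift: 0 before day 3, 1 from day 11 on.
driftRamp <- function(day) pmin(pmax((day - 3) / 8, 0), 1)

# Lactose effect indicator per (group, day): phase II for model/control/test,
# phase III for model/control only; test reverts to the shared trend.
lactoseActive <- function(group, day) {
  ph <- as.character(phaseOfDay(day))
  (ph == "II" & group %in% c("model", "control", "test")) |
    (ph == "III" & group %in% c("model", "control"))
}

syntheticTaxonomy <- function(baseline) {
  nf <- length(baseline)
  ord <- order(baseline, decreasing = TRUE)
  cls <- rep(NA_character_, nf)
  gen <- rep(NA_character_, nf)
  top50 <- ord[seq_len(min(50, nf))]
  bact <- top50[seq_len(min(35, length(top50)))]
  cls[bact] <- "Bacteroidia"; gen[bact] <- "Bacteroides"
  lacto <- top50[min(36, length(top50))]
  cls[lacto] <- "Bacilli"; gen[lacto] <- "Lactobacillus"
  restClasses <- c("Clostridia", "Bacilli", "Verrucomicrobiae",
                   "Gammaproteobacteria", "Coriobacteriia")
  fill <- is.na(cls)
  cls[fill] <- rep_len(restClasses, sum(fill))
  gen[fill] <- paste0("g_", cls[fill])
  conf <- runif(nf, 0.5, 0.99)
  conf[bact[1]] <- 0.90   # the dominant Bacteroides-like ASV
  conf[lacto] <- 0.92
  species <- ifelse(gen == "Bacteroides", "Bacteroides acidifaciens",
                    ifelse(gen == "Lactobacillus", "Lactobacillus murinus",
                           NA_character_))
  data.frame(
    lineage = paste0("d__Bacteria;c__", cls, ";g__", gen),
    class = cls, genus = gen, species = species, confidence = round(conf, 2),
    row.names = paste0("ASV", sprintf("%03d", seq_len(nf))))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a synthetic 21-day study
#'
#' @param config a [studyConfig()]
#' @return a [FeatureTable-class] with `group`, `day`, `mouse`, `cage`
#'   metadata and taxonomy, plus latent ground truth in `metadata(x)`:
#'   `bacteroides_block` and `lactobacillus_feature` ids
#' @examples
#' ft <- simulateStudy(studyConfig(nMicePerGroup = 2, nFeatures = 40))
#' ft
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  withSeed(config$seed, {
    nf <- config$nFeatures
    baseline <- rnorm(nf, 0, config$baselineSdlog)
    tax <- syntheticTaxonomy(baseline)
    block <- which(tax$genus == "Bacteroides")
    lacto <- which(tax$genus == "Lactobacillus")
    drift <- numeric(nf)
    drift[block] <- config$driftMagnitude
    eff <- numeric(nf)
    eff[block] <- config$bacteroidesSuppression
    eff[lacto] <- config$lactobacillusBoost

    cohortDays <- list(A = c(1, 5, 9, 13, 17, 21), B = c(3, 7, 11, 15, 19))
    rows <- list(); counts <- list()
    for (g in config$groups) {
      for (m in seq_len(config$nMicePerGroup)) {
        mouseEff <- rnorm(nf, 0, config$mouseSd)
        cage <- paste0(g, "_c", (m - 1) %/% 5 + 1)
        cageEff <- if (config$cageEffectSd > 0)
          rnorm(1, 0, config$cageEffectSd) else 0
        days <- if (config$sampling == "alternating")
          cohortDays[[if (m %% 2 == 1) "A" else "B"]] else config$samplingDays
        for (d in days) {
          lam <- baseline + mouseEff + cageEff + drift * driftRamp(d) +
            if (lactoseActive(g, d)) eff else 0
          alpha <- exp(lam)
          alpha <- alpha / sum(alpha) * config$concentration
          p <- rdirichlet1(alpha)
          depth <- max(100L, as.integer(round(rlnorm(
            1, log(config$depthMean) - config$depthSdlog^2 / 2,
            config$depthSdlog))))
          counts[[length(counts) + 1L]] <- as.integer(rmultinom(1, depth, p))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_m%02d_d%02d", g, m, d),
            group = g, day = d, mouse = sprintf("%s_m%02d", g, m),
            cage = cage)
        }
      }
    }
    meta <- do.call(rbind, rows)
    rownames(meta) <- meta$sample_id
    mat <- do.call(cbind, counts)
    dimnames(mat) <- list(rownames(tax), meta$sample_id)
    ft <- FeatureTable(mat, meta, tax)
    S4Vectors::metadata(ft) <- list(
      bacteroides_block = rownames(tax)[block],
      lactobacillus_feature = rownames(tax)[lacto],
      config = config)
    ft
  })
}

#' Null study (no effects, no drift)
#'
#' [simulateStudy()] with the lactose effects and the shared drift set to
#' zero; groups are exchangeable by construction, so any between-group test
#' measures its type-I error.
#'
#' @param config a [studyConfig()]
#' @return a [FeatureTable-class]
#' @export
nullStudy <- function(config) {
  config$bacteroidesSuppression <- 0
  config$lactobacillusBoost <- 0
  config$driftMagnitude <- 0
  simulateStudy(config)
}

#' Gaussian data from a known sparse precision graph
#'
#' Builds a sparse positive-definite precision matrix with the requested
#' structure, draws `n` multivariate normal samples from its inverse, and
#' returns the ground-truth adjacency for recovery scoring.
#'
#' Structures: `"band"` (within-`bandwidth` neighbours coupled, default
#' bandwidth 1, value `strength`), `"chain"` (bandwidth-1 band), `"random"`
#' (Erdos-Renyi off-diagonal support at `density`, diagonally dominated).
#'
#' @param p number of features (>= 2)
#' @param n number of samples (>= 2)
#' @param graph `"band"`, `"chain"` or `"random"`
#' @param bandwidth band half-width for `"band"` (default 1)
#' @param strength off-diagonal precision value (default 0.3)
#' @param density edge density for `"random"` (default 0.04)
#' @param seed integer seed
#' @return list with `data` (n x p), `precision`, `adjacency` (true 0/1)
#' @export
simulatePrecisionGraphData <- function(p, n,
                                       graph = c("band", "chain", "random"),
                                       bandwidth = 1, strength = 0.3,
                                       density = 0.04, seed = 1) {
  graph <- match.arg(graph)
  stopifnot(p >= 2, n >= 2)
  Theta <- diag(p)
  if (graph %in% c("band", "chain")) {
    bw <- if (graph == "chain") 1 else bandwidth
    for (d in seq_len(bw)) {
      v <- strength / d
      idx <- seq_len(p - d)
      Theta[cbind(idx, idx + d)] <- v
      Theta[cbind(idx + d, idx)] <- v
    }
    if (min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("band too strong to remain positive definite; lower 'strength'")
  } else {
    nePossible <- p * (p - 1) / 2
    ne <- round(density * nePossible)
    if (ne < 1 || ne > nePossible) stop("infeasible edge density")
    withSeed(seed, {
      pick <- sample.int(nePossible, ne)
      ut <- which(upper.tri(Theta))
      Theta[ut[pick]] <- strength
    })
    Theta <- (Theta + t(Theta)) / 2
    diag(Theta) <- 0
    dom <- rowSums(abs(Theta))
    diag(Theta) <- dom + 0.1
  }
  A <- (abs(Theta) > 1e-12) * 1
  diag(A) <- 0
  Sigma <- solve(Theta)
  Sigma <- (Sigma + t(Sigma)) / 2
  R <- chol(Sigma)
  X <- withSeed(seed + 1, matrix(rnorm(n * p), n, p) %*% R)
  colnames(X) <- colnames(A) <- rownames(A) <- paste0("F", seq_len(p))
  dimnames(Theta) <- dimnames(A)
  list(data = X, precision = Theta, adjacency = A)
}

#' F1 score of a recovered adjacency against the truth
#' @param estimate,truth symmetric 0/1 adjacency matrices
#' @return F1 = 2*precision*recall / (precision + recall) over the upper
#'   triangle (0 when no edges are recovered)
#' @export
edgeF1 <- function(estimate, truth) {
  e <- estimate[upper.tri(estimate)] > 0
  t_ <- truth[upper.tri(truth)] > 0
  tp <- sum(e & t_)
  if (tp == 0) return(0)
  prec <- tp / sum(e)
  rec <- tp / sum(t_)
  2 * prec * rec / (prec + rec)
}

#' Qualitative PCo1 recovery pattern of the 21-day design
#'
#' Checks, on an ordination of a study table, the trajectory pattern the
#' design is built to produce: (i) the untreated group drifts along PCo1
#' between the baseline days (1, 3) and days 7-11 by more than the baseline
#' spread; (ii) during days 7-11 the untreated group sits beyond the
#' lactose-fed groups (model, control); (iii) in the treatment phase (days
#' 13, 15) the test group closes more than half of the model group's gap to
#' the untreated group. The axis is oriented so the untreated drift is
#' positive.
#'
#' @param pco1 PCo1 coordinate per sample
#' @param metadata data.frame with `group` and `day` per sample
#' @return list of logicals `drift`, `separation`, `catchup` and overall
#'   `pass`
#' @export
trajectoryPattern <- function(pco1, metadata) {
  m <- function(g, days) mean(pco1[metadata$group == g & metadata$day %in% days])
  s <- sign(m("untreated", c(7, 9, 11)) - m("untreated", c(1, 3)))
  if (s == 0) s <- 1
  x <- s * pco1
  m <- function(g, days) mean(x[metadata$group == g & metadata$day %in% days])
  base_sd <- stats::sd(x[metadata$group == "untreated" & metadata$day <= 3])
  driftU <- m("untreated", c(7, 9, 11)) - m("untreated", c(1, 3))
  drift <- driftU > base_sd
  separation <- m("untreated", c(7, 9, 11)) > m("model", c(7, 9, 11)) &&
    m("untreated", c(7, 9, 11)) > m("control", c(7, 9, 11))
  gap_t <- abs(m("test", c(13, 15)) - m("untreated", c(13, 15)))
  gap_m <- abs(m("model", c(13, 15)) - m("untreated", c(13, 15)))
  catchup <- gap_t < 0.5 * gap_m
  list(drift = drift, separation = separation, catchup = catchup,
       pass = drift && separation && catchup)
}
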