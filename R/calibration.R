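# Study-level Monte-Carlo harnesses used by the test suite and the
# acceptance script: type-I calibration of the per-day group tests on null
# studies, and the qualitative PCo1 recovery pattern rate on default-effect
# studies.

jsdPcoaPipeline <- function(ft, depth, seed, pseudocount = 1e-6) {
  rar <- suppressMessages(rarefyCounts(ft, depth = depth, seed = seed))
  ord <- classicalPcoa(pairwiseJsd(relativeAbundance(rar, pseudocount)), 2)
  list(rarefied = rar, ordination = ord,
       pco1 = ordCoordinates(ord)[, 1], meta = sampleData(rar))
}

#' Default scaled study design for type-I calibration
#'
#' Two exchangeable groups of 15 mice sampled on a single day, 60 features at
#' mean depth 1200. One cell per replicate keeps the pooled rejection count
#' binomial (cells from the same replicate would share mice and one
#' ordination, and therefore be correlated), and cells of about 15 vs 15
#' samples exercise the Mann-Whitney normal-approximation branch, whose
#' attainable size at the 0.05 level is 0.0502 (by exact enumeration of the
#' null U distribution) — essentially nominal, unlike the heavily discrete
#' exact branch at small n.
#'
#' @param seed integer seed
#' @return a [studyConfig()]
#' @export
calibrationConfig <- function(seed = 1) {
  studyConfig(nMicePerGroup = 15, groups = c("untreated", "model"),
              nFeatures = 60, depthMean = 1200, sampling = "daily",
              samplingDays = 3, seed = seed)
}

#' Type-I error calibration of the per-day group tests on null studies
#'
#' Simulates `reps` null studies (all effects and drift zero), runs each
#' through rarefaction, sqrt-JSD, PCoA and the per-day Mann-Whitney tests on
#' PCo1, and reports the pooled per-cell rejection rate at level `alpha`
#' together with the 95% binomial interval around the nominal level.
#'
#' @param reps number of replicate null studies (default 500)
#' @param alpha nominal level (default 0.05)
#' @param config base [studyConfig()] (default [calibrationConfig()]); its
#'   effects are zeroed via [nullStudy()]
#' @param depth rarefaction depth (default 800)
#' @param seed integer master seed
#' @return list with `rate`, `n_cells`, `rejections`, `ci` (the binomial
#'   interval around `alpha`), and `within` (rate inside the interval)
#' @export
calibrateTypeI <- function(reps = 500, alpha = 0.05,
                           config = calibrationConfig(), depth = 800,
                           seed = 1) {
  seeds <- childSeeds(seed, 2 * reps)
  rej <- 0L; ncell <- 0L
  for (r in seq_len(reps)) {
    config$seed <- seeds[r]
    ft <- nullStudy(config)
    pl <- jsdPcoaPipeline(ft, depth, seeds[reps + r])
    tests <- perDayGroupTests(pl$pco1, pl$meta)
    ok <- !is.na(tests$p)
    ncell <- ncell + sum(ok)
    rej <- rej + sum(tests$p[ok] <= alpha)
  }
  rate <- rej / ncell
  half <- 1.96 * sqrt(alpha * (1 - alpha) / ncell)
  ci <- c(alpha - half, alpha + half)
  list(rate = rate, n_cells = ncell, rejections = rej, ci = ci,
       within = rate >= ci[1] && rate <= ci[2])
}

#' Rate of qualitative PCo1 pattern recovery on default-effect studies
#'
#' For each of `nSeeds` seeds, simulates a default study, runs the
#' rarefaction / sqrt-JSD / PCoA pipeline and evaluates
#' [trajectoryPattern()]; returns the fraction of seeds reproducing the full
#' pattern (untreated drift by days 7-11, lactose-group separation, test
#' catch-up in the treatment phase).
#'
#' @param nSeeds number of studies (default 50)
#' @param config base [studyConfig()] (default defaults)
#' @param depth rarefaction depth (default 4000)
#' @param seed integer master seed
#' @return list with `rate` and the per-seed logical vector `pass`
#' @export
patternRecoveryRate <- function(nSeeds = 50, config = studyConfig(),
                                depth = 4000, seed = 1) {
  seeds <- childSeeds(seed, 2 * nSeeds)
  pass <- logical(nSeeds)
  for (i in seq_len(nSeeds)) {
    config$seed <- seeds[i]
    ft <- simulateStudy(config)
    pl <- jsdPcoaPipeline(ft, depth, seeds[nSeeds + i])
    pass[i] <- trajectoryPattern(pl$pco1, pl$meta)$pass
  }
  list(rate = mean(pass), pass = pass)
}
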