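fmtNum <- function(x) format(x, digits = 9, trim = TRUE, scientific = FALSE)

writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from tab-separated files
#'
#' The count matrix may be features x samples or samples x features; the
#' orientation is auto-detected from the metadata sample ids. Duplicate ids,
#' non-integer counts and id mismatches are rejected with informative errors.
#'
#' @param countsPath TSV with ids in the first column and ids as the header
#' @param metadataPath TSV with a `sample_id` column (or ids in the first
#'   column) and metadata columns
#' @param taxonomyPath optional TSV with a `feature_id` column
#' @return a [FeatureTable-class]
#' @export
readFeatureTable <- function(countsPath, metadataPath, taxonomyPath = NULL) {
  raw <- utils::read.delim(countsPath, check.names = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in counts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts in ", countsPath)
  rownames(m) <- ids
  meta <- utils::read.delim(metadataPath, check.names = FALSE)
  if (!"sample_id" %in% names(meta)) names(meta)[1] <- "sample_id"
  tax <- if (!is.null(taxonomyPath)) {
    tx <- utils::read.delim(taxonomyPath, check.names = FALSE)
    if (!"feature_id" %in% names(tx)) names(tx)[1] <- "feature_id"
    tx
  }
  FeatureTable(m, meta, tax)
}

#' Write a feature table (counts, metadata, taxonomy) as TSV
#'
#' @param x a [FeatureTable-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (default "feature_table")
#' @return invisibly, the written paths
#' @export
writeFeatureTable <- function(x, dir, prefix = "feature_table") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- asvCounts(x)
  cp <- file.path(dir, paste0(prefix, "_counts.tsv"))
  writeTsv(data.frame(feature_id = rownames(m), m, check.names = FALSE), cp)
  mp <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  writeTsv(data.frame(sample_id = colnames(x), sampleData(x),
                      check.names = FALSE), mp)
  paths <- c(counts = cp, metadata = mp)
  tx <- taxonomy(x)
  if (ncol(tx)) {
    tp <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
    writeTsv(data.frame(feature_id = rownames(x), tx, check.names = FALSE), tp)
    paths <- c(paths, taxonomy = tp)
  }
  invisible(paths)
}

#' Square labelled distance matrix text I/O
#' @param D symmetric labelled matrix
#' @param path TSV path
#' @return `readDistanceMatrix`: the matrix; `writeDistanceMatrix`: the path,
#'   invisibly
#' @export
writeDistanceMatrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D),
                   apply(D, 2, fmtNum), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Write an ordination as tidy text
#' @param ord an [Ordination-class]
#' @param path TSV path
#' @export
writeOrdination <- function(ord, path) {
  co <- ordCoordinates(ord)
  evPos <- eigenvalues(ord)[eigenvalues(ord) > 0]
  df <- do.call(rbind, lapply(seq_len(ncol(co)), function(j)
    data.frame(sample_id = rownames(co), axis = colnames(co)[j],
               coordinate = co[, j], eigenvalue = evPos[j],
               proportion = proportionExplained(ord)[j])))
  writeTsv(df, path)
}

#' Write a network edge list
#' @param net a [NetworkModel-class]
#' @param path TSV path
#' @export
writeEdgeList <- function(net, path) {
  A <- adjacency(net)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  writeTsv(data.frame(node_a = rownames(A)[idx[, 1]],
                      node_b = colnames(A)[idx[, 2]]), path)
}

#' Write a trajectory table as tidy long text
#' @param traj a [runScenario()] output
#' @param path TSV path
#' @export
writeTrajectory <- function(traj, path) {
  vars <- setdiff(names(traj), c("time_h", "arm", "scenario_id"))
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(time_h = traj$time_h, variable = v,
               value = as.numeric(traj[[v]]), arm = traj$arm,
               scenario_id = traj$scenario_id)))
  writeTsv(long, path)
}

stageLog <- function(stage, msg, t0) {
  message(sprintf("[%s] INFO %s (%.1fs elapsed)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run the microbiome pipeline end to end
#'
#' Synthesis (or a supplied table) -> rarefaction -> pseudocounted relative
#' abundance -> pairwise sqrt-JSD -> PCoA -> Loess PCo1 trajectories ->
#' per-day group tests -> condition networks, with structured stage logs and
#' a JSON run manifest recording the seed and configuration.
#'
#' @param config list with optional entries `study` (arguments to
#'   [studyConfig()]), `table` (a ready [FeatureTable-class], bypassing
#'   synthesis), `depth` (rarefaction depth, default 4000), `pseudocount`
#'   (default 1e-6), `span` (default 0.75), `network` (arguments to
#'   [starsSelect()] via [conditionNetworks()]; set `config$runNetwork =
#'   FALSE` to skip the network stage)
#' @param out optional output directory; when given, all artifacts are
#'   written as tab-separated text plus `manifest.json`
#' @param seed integer master seed for every stochastic stage
#' @return (invisibly) list with the intermediate objects and the manifest
#' @export
runPipeline <- function(config = list(), out = NULL, seed = 1) {
  t0 <- as.numeric(Sys.time())
  seeds <- childSeeds(seed, 4)
  depth <- config$depth %||% 4000
  eps <- config$pseudocount %||% 1e-6
  span <- config$span %||% 0.75

  if (is.null(config$table)) {
    sc <- do.call(studyConfig, c(config$study %||% list(),
                                 list(seed = seeds[1])))
    ft <- simulateStudy(sc)
    stageLog("synth", sprintf("%d features x %d samples", nrow(ft), ncol(ft)), t0)
  } else {
    ft <- config$table
    stageLog("input", sprintf("%d features x %d samples", nrow(ft), ncol(ft)), t0)
  }
  rar <- rarefyCounts(ft, depth = depth, seed = seeds[2])
  stageLog("rarefy", sprintf("%d -> %d samples at depth %d",
                             ncol(ft), ncol(rar), depth), t0)
  prof <- relativeAbundance(rar, eps)
  D <- pairwiseJsd(prof)
  stageLog("distance", sprintf("%d x %d sqrt-JSD matrix", nrow(D), ncol(D)), t0)
  ord <- classicalPcoa(D, k = 2)
  stageLog("pcoa", sprintf("PCo1 explains %.1f%%",
                           100 * proportionExplained(ord)[1]), t0)
  meta <- sampleData(rar)
  traj <- loessTrajectory(ordCoordinates(ord)[, 1], meta$day, meta$group,
                          span = span)
  tests <- perDayGroupTests(ordCoordinates(ord)[, 1], meta)
  stageLog("tests", sprintf("%d cells tested, %d with q < 0.05",
                            sum(!is.na(tests$p)),
                            sum(tests$q < 0.05, na.rm = TRUE)), t0)
  nets <- NULL
  if (!isFALSE(config$runNetwork)) {
    nets <- do.call(conditionNetworks,
                    c(list(x = rar, seed = seeds[3], pseudocount = eps),
                      config$network %||% list()))
    stageLog("network", paste(vapply(nets$networks, function(n)
      sprintf("%d edges", sum(adjacency(n)) / 2), ""), collapse = ", "), t0)
  }
  manifest <- list(
    command = "runPipeline", package_version = "0.1.0",
    seed = seed, stage_seeds = seeds,
    config = list(depth = depth, pseudocount = eps, span = span,
                  study = config$study %||% list()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_samples = ncol(rar), n_features = nrow(rar))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeFeatureTable(rar, out, "rarefied")
    writeDistanceMatrix(D, file.path(out, "jsd_distance.tsv"))
    writeOrdination(ord, file.path(out, "ordination.tsv"))
    writeTsv(traj, file.path(out, "trajectory.tsv"))
    writeTsv(tests, file.path(out, "group_tests.tsv"))
    if (!is.null(nets)) {
      for (nm in names(nets$networks))
        writeEdgeList(nets$networks[[nm]],
                      file.path(out, paste0("network_", nm, "_edges.tsv")))
      writeTsv(nets$nodes, file.path(out, "network_nodes.tsv"))
    }
    manifest$outputs <- list.files(out)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stageLog("write", paste("outputs in", out), t0)
  }
  invisible(list(table = ft, rarefied = rar, distance = D, ordination = ord,
                 trajectory = traj, tests = tests, networks = nets,
                 manifest = manifest))
}
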