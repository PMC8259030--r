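#' FeatureTable: an ASV count table with sample metadata and taxonomy
#'
#' Thin subclass of [SummarizedExperiment::SummarizedExperiment] holding a
#' features x samples integer count assay named \code{"counts"}, per-sample
#' metadata in \code{colData} (for study designs: \code{group}, \code{day},
#' \code{mouse}, \code{cage}) and per-feature taxonomy in \code{rowData}
#' (\code{lineage}, \code{class}, \code{genus}, \code{confidence}).
#'
#' Validity requires non-negative finite integer counts and unique feature and
#' sample identifiers. Analysis functions that need particular metadata columns
#' check for them at call time, so plain tables (e.g. for the network oracle)
#' are also valid \code{FeatureTable}s.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (!is.numeric(m)) return("counts must be numeric")
  if (any(!is.finite(m))) return("counts must be finite")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) return("counts must be integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids must be present and unique")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param counts numeric matrix of non-negative integer counts. Orientation is
#'   auto-detected from the id sets in `metadata`: if rows match sample ids the
#'   matrix is transposed so features end up in rows.
#' @param metadata `data.frame` of per-sample metadata, one row per sample,
#'   with sample ids as row names (or a `sample_id` column).
#' @param taxonomy optional `data.frame` of per-feature taxonomy with feature
#'   ids as row names (or a `feature_id` column); columns typically `lineage`,
#'   `class`, `genus`, `confidence`.
#' @return a [FeatureTable-class] object (features in rows, samples in columns).
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("ASV", 1:3), paste0("S", 1:4)))
#' md <- data.frame(row.names = paste0("S", 1:4),
#'                  group = "untreated", day = c(1, 1, 3, 3),
#'                  mouse = paste0("m", 1:4), cage = "c1")
#' ft <- FeatureTable(m, md)
#' @export
FeatureTable <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry both row and column names")
  if (!is.null(metadata$sample_id)) {
    rownames(metadata) <- metadata$sample_id
    metadata$sample_id <- NULL
  }
  sids <- rownames(metadata)
  if (all(rownames(counts) %in% sids) && !all(colnames(counts) %in% sids)) {
    counts <- t(counts)  # samples were in rows
  }
  if (!setequal(colnames(counts), sids)) {
    missing <- setdiff(colnames(counts), sids)
    extra <- setdiff(sids, colnames(counts))
    stop("sample ids in counts and metadata disagree: ",
         paste(c(missing, extra), collapse = ", "))
  }
  metadata <- metadata[colnames(counts), , drop = FALSE]
  rd <- NULL
  if (!is.null(taxonomy)) {
    if (!is.null(taxonomy$feature_id)) {
      rownames(taxonomy) <- taxonomy$feature_id
      taxonomy$feature_id <- NULL
    }
    if (!all(rownames(counts) %in% rownames(taxonomy)))
      stop("taxonomy is missing features: ",
           paste(utils::head(setdiff(rownames(counts), rownames(taxonomy)), 5),
                 collapse = ", "))
    rd <- S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(metadata),
    rowData = rd)
  methods::new("FeatureTable", se)
}

#' @describeIn FeatureTable integer count matrix (features x samples)
#' @param x a `FeatureTable`
#' @export
asvCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn FeatureTable per-sample metadata as a base `data.frame`
#' @export
sampleData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn FeatureTable per-feature taxonomy as a base `data.frame`
#' @export
taxonomy <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object), "features x", ncol(object), "samples\n")
  cat("  depth range:", paste(range(colSums(asvCounts(object))), collapse = " - "), "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("group" %in% colnames(cd))
    cat("  groups:", paste(names(table(cd$group)), table(cd$group),
                           sep = "=", collapse = ", "), "\n")
})

#' Ordination: principal coordinates of a distance matrix
#'
#' Classical-scaling result: column-centred sample coordinates on the retained
#' positive axes, the full eigenvalue spectrum (negative eigenvalues reported,
#' not corrected) and the proportion of positive-eigenvalue variance explained.
#'
#' @slot coordinates samples x k matrix of principal coordinates
#' @slot eigenvalues full eigenvalue vector, sorted decreasing
#' @slot proportionExplained per-retained-axis share of sum of positive eigenvalues
#' @exportClass Ordination
setClass("Ordination", representation(
  coordinates = "matrix",
  eigenvalues = "numeric",
  proportionExplained = "numeric"))

setValidity("Ordination", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strict = FALSE) && is.unsorted(-ev))
    return("eigenvalues must be sorted decreasing")
  cm <- colMeans(object@coordinates)
  if (length(cm) && max(abs(cm)) > 1e-6)
    return("coordinates must be column-centred")
  TRUE
})

#' @describeIn Ordination sample coordinate matrix
#' @param x an `Ordination`
#' @export
ordCoordinates <- function(x) x@coordinates

#' @describeIn Ordination full eigenvalue spectrum
#' @export
eigenvalues <- function(x) x@eigenvalues

#' @describeIn Ordination proportion of variance explained per retained axis
#' @export
proportionExplained <- function(x) x@proportionExplained

setMethod("show", "Ordination", function(object) {
  cat("Ordination:", nrow(object@coordinates), "samples,",
      ncol(object@coordinates), "axes\n")
  pe <- object@proportionExplained
  cat("  explained:", paste(sprintf("%.1f%%", 100 * utils::head(pe, 3)),
                            collapse = ", "), "\n")
  if (any(object@eigenvalues < 0))
    cat("  note:", sum(object@eigenvalues < 0), "negative eigenvalues\n")
})

#' NetworkModel: a stability-selected sparse association network
#'
#' @slot adjacency symmetric unweighted 0/1 matrix over the filtered features
#' @slot nodes data.frame of node annotations (class, genus, mean abundances,
#'   top-abundance flag)
#' @slot selectedLambda penalty chosen by StARS
#' @slot lambdaPath the full penalty path (decreasing)
#' @slot instabilityPath per-lambda monotonized edge instability
#'   `mean_e 2*xi_e*(1-xi_e)`, bounded by 0.5
#' @slot converged FALSE when no path point met the instability criterion and
#'   the densest end was returned
#' @exportClass NetworkModel
setClass("NetworkModel", representation(
  adjacency = "matrix",
  nodes = "data.frame",
  selectedLambda = "numeric",
  lambdaPath = "numeric",
  instabilityPath = "numeric",
  converged = "logical"))

setValidity("NetworkModel", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (!isTRUE(all.equal(A, t(A)))) return("adjacency must be symmetric")
  if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
  if (!all(A %in% c(0, 1))) return("adjacency must be 0/1")
  ip <- object@instabilityPath
  if (length(ip) && (min(ip) < -1e-12 || max(ip) > 0.5 + 1e-12))
    return("instability values must lie in [0, 0.5]")
  TRUE
})

#' @describeIn NetworkModel unweighted adjacency matrix
#' @param x a `NetworkModel`
#' @export
adjacency <- function(x) x@adjacency

#' @describeIn NetworkModel node annotation table
#' @export
nodeTable <- function(x) x@nodes

#' @describeIn NetworkModel StARS-selected penalty
#' @export
selectedLambda <- function(x) x@selectedLambda

#' @describeIn NetworkModel per-lambda monotonized instability along the path
#' @export
instabilityPath <- function(x) x@instabilityPath

setMethod("show", "NetworkModel", function(object) {
  p <- nrow(object@adjacency)
  cat("NetworkModel:", p, "nodes,", sum(object@adjacency) / 2, "edges\n")
  cat("  lambda =", format(object@selectedLambda, digits = 4),
      if (!object@converged) "(instability criterion not met; densest path end)\n"
      else "\n")
})
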