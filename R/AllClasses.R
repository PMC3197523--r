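#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom Rcpp sourceCpp
#' @useDynLib sutureGIC, .registration = TRUE
NULL

#' Probe-level expression container
#'
#' A \linkS4class{SummarizedExperiment} holding log2 probe intensities
#' (probes x samples) in an assay named \code{"exprs"}, with the
#' probe-to-gene (probe-set) map in \code{rowData()$gene_id} and the sample
#' annotation (group, age, sex, batch) in \code{colData()}.
#'
#' @seealso [ProbeExperiment()] for the constructor,
#'   [probeGeneMap()], [probeValues()]
#' @export
setClass("ProbeExperiment", contains = "SummarizedExperiment")

#' Gene-level (probe-set summarized) expression container
#'
#' A \linkS4class{SummarizedExperiment} of log2 expression values, one row
#' per gene, produced by [medianPolishSummarize()].
#'
#' @seealso [GeneExperiment()], [geneValues()]
#' @export
setClass("GeneExperiment", contains = "SummarizedExperiment")

setValidity("ProbeExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else if (!all(is.finite(assay(object, "exprs"))))
    msg <- c(msg, "probe intensities must all be finite")
  ids <- rownames(object)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  gid <- rowData(object)$gene_id
  if (is.null(gid) || anyNA(gid))
    msg <- c(msg, "rowData()$gene_id must map every probe to a gene")
  if (length(msg)) msg else TRUE
})

setValidity("GeneExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  ids <- rownames(object)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeExperiment
#'
#' @param values numeric matrix of log2 probe intensities, probes x samples,
#'   with probe ids as rownames and sample ids as colnames.
#' @param gene_id character vector, one gene id per probe (the probe-set map).
#' @param annotation optional data.frame of per-sample covariates with a
#'   \code{sample_id} column matching \code{colnames(values)}; stored as
#'   \code{colData}.
#' @return A [ProbeExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
#' pe <- ProbeExperiment(m, gene_id = c("g1", "g1", "g2", "g2"))
#' probeGeneMap(pe)
#' @export
ProbeExperiment <- function(values, gene_id, annotation = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("probe intensities must be a finite numeric matrix")
  if (length(gene_id) != nrow(values))
    stop("'gene_id' must have one entry per probe row")
  cd <- NULL
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (!"sample_id" %in% names(annotation))
      stop("annotation must have a 'sample_id' column")
    idx <- match(colnames(values), annotation$sample_id)
    if (anyNA(idx))
      stop("annotation is missing samples: ",
           paste(setdiff(colnames(values), annotation$sample_id), collapse = ", "))
    cd <- S4Vectors::DataFrame(annotation[idx, , drop = FALSE],
                               row.names = colnames(values))
  }
  args <- list(assays = list(exprs = values),
               rowData = DataFrame(gene_id = as.character(gene_id),
                                   row.names = rownames(values)))
  if (!is.null(cd)) args$colData <- cd
  new("ProbeExperiment", do.call(SummarizedExperiment, args))
}

#' Construct a GeneExperiment
#'
#' @param values numeric matrix of log2 expression, genes x samples.
#' @param annotation optional per-sample annotation (see [ProbeExperiment()]).
#' @return A [GeneExperiment-class] object.
#' @export
GeneExperiment <- function(values, annotation = NULL) {
  values <- as.matrix(values)
  cd <- NULL
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    idx <- match(colnames(values), annotation$sample_id)
    cd <- S4Vectors::DataFrame(annotation[idx, , drop = FALSE],
                               row.names = colnames(values))
  }
  args <- list(assays = list(exprs = values))
  if (!is.null(cd)) args$colData <- cd
  new("GeneExperiment", do.call(SummarizedExperiment, args))
}

#' Accessors for expression containers
#'
#' \code{probeValues()} and \code{geneValues()} return the log2 expression
#' matrix; \code{probeGeneMap()} returns the two-column probe-to-gene map;
#' \code{sampleAnnotation()} returns the per-sample covariate table.
#'
#' @param x a [ProbeExperiment-class] or [GeneExperiment-class].
#' @return A matrix or data.frame, see above.
#' @export
probeValues <- function(x) {
  stopifnot(is(x, "ProbeExperiment"))
  assay(x, "exprs")
}

#' @rdname probeValues
#' @export
geneValues <- function(x) {
  stopifnot(is(x, "GeneExperiment"))
  assay(x, "exprs")
}

#' @rdname probeValues
#' @export
probeGeneMap <- function(x) {
  stopifnot(is(x, "ProbeExperiment"))
  data.frame(probe_id = rownames(x),
             gene_id = rowData(x)$gene_id,
             stringsAsFactors = FALSE)
}

#' @rdname probeValues
#' @export
sampleAnnotation <- function(x) {
  as.data.frame(colData(x))
}

setMethod("show", "ProbeExperiment", function(object) {
  cat("ProbeExperiment:", nrow(object), "probes x", ncol(object), "samples;",
      length(unique(rowData(object)$gene_id)), "genes\n")
  callNextMethod()
})

#' GIC screening result
#'
#' Holds per-gene Gene Information Content scores together with the
#' permutation null used to derive the significance cutoff. Created by
#' [gicAnalysis()].
#'
#' @slot scores \code{DataFrame} with columns \code{gene_id}, \code{gic},
#'   \code{n_probes}, \code{single_probe}, \code{degenerate}, \code{rank},
#'   \code{passes_cutoff}.
#' @slot cutoff numeric(1), the null-quantile cutoff on the GIC scale.
#' @slot nullScores numeric, pooled permuted GIC scores.
#' @slot nPermutations integer(1).
#' @slot probability numeric(1), the null quantile used (default 0.99).
#' @slot seed integer(1) seed used for the permutations.
#' @seealso [gicAnalysis()], [gicScores()], [gicCutoff()], [rankAndSelect()]
#' @export
setClass("GicResult",
         representation(scores = "DataFrame", cutoff = "numeric",
                        nullScores = "numeric", nPermutations = "integer",
                        probability = "numeric", seed = "integer"))

setValidity("GicResult", function(object) {
  msg <- character()
  sc <- object@scores
  need <- c("gene_id", "gic", "n_probes", "rank", "passes_cutoff")
  if (!all(need %in% colnames(sc)))
    msg <- c(msg, paste("scores must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(sc$gic < 0 | sc$gic > 1))
      msg <- c(msg, "gic scores must lie in [0, 1]")
    if (!setequal(sc$rank, seq_len(nrow(sc))))
      msg <- c(msg, "ranks must be a permutation of 1..n_genes")
    if (!identical(sc$passes_cutoff, sc$gic > object@cutoff))
      msg <- c(msg, "passes_cutoff must equal gic > cutoff")
  }
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn GicResult per-gene score table as a data.frame
#' @param x,object a \code{GicResult}
#' @export
gicScores <- function(x) {
  stopifnot(is(x, "GicResult"))
  as.data.frame(x@scores)
}

#' @describeIn GicResult the permutation-derived GIC cutoff
#' @export
gicCutoff <- function(x) {
  stopifnot(is(x, "GicResult"))
  x@cutoff
}

#' @describeIn GicResult pooled permuted GIC scores forming the null
#' @export
gicNullScores <- function(x) {
  stopifnot(is(x, "GicResult"))
  x@nullScores
}

setMethod("show", "GicResult", function(object) {
  sc <- object@scores
  cat("GicResult:", nrow(sc), "genes\n")
  cat(sprintf("  cutoff %.4f (%g%% quantile of %d permutations, %d pooled null scores)\n",
              object@cutoff, 100 * object@probability, object@nPermutations,
              length(object@nullScores)))
  cat(sprintf("  %d genes pass the cutoff; %d single-probe genes flagged\n",
              sum(sc$passes_cutoff), sum(sc$single_probe)))
})
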