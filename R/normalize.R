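#' Quantile normalization of a probe matrix
#'
#' Forces every sample (column) to share one distribution: the reference is
#' the row-wise mean of the per-column sorted values, and each value is
#' replaced by the reference value at its within-column rank. Ties get the
#' mean of the reference values spanned by their (average) rank, so the
#' result is deterministic. This is the between-array step of the classic
#' RMA preprocessing chain; inputs are assumed already log2 scale.
#'
#' @param x a [ProbeExperiment-class] or numeric matrix with >= 2 columns.
#' @return Same type as the input, normalized; row/column identity kept.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(3, 4, 5)))
#' @export
quantileNormalize <- function(x) {
  if (is(x, "ProbeExperiment")) {
    out <- x
    SummarizedExperiment::assay(out, "exprs") <-
      quantileNormalize(probeValues(x))
    return(out)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 samples")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  ref <- rowMeans(apply(x, 2, sort, method = "radix"))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Median-polish probe-set summarization
#'
#' Fits the additive model \code{value = overall + probe + sample} per gene
#' by Tukey median polish (rows then columns, midpoint medians, relative
#' tolerance \code{eps} on the sum of absolute residuals, at most
#' \code{maxiter} sweeps) and reports \code{overall + sample effect} as the
#' gene's expression — the summarization step of RMA, which absorbs
#' probe-specific affinity offsets. Single-probe genes pass through
#' unchanged.
#'
#' @param x a [ProbeExperiment-class].
#' @param eps convergence tolerance on the residual change.
#' @param maxiter maximum polish sweeps.
#' @return A [GeneExperiment-class], genes in first-appearance order of the
#'   probe map, carrying the sample annotation forward.
#' @export
medianPolishSummarize <- function(x, eps = 1e-6, maxiter = 20L) {
  stopifnot(is(x, "ProbeExperiment"))
  values <- probeValues(x)
  gene <- rowData(x)$gene_id
  gl <- unique(gene)
  idx <- split(seq_len(nrow(values)), factor(gene, levels = gl))
  if (any(lengths(idx) == 0)) stop("probe map lists a gene with zero probes")
  out <- matrix(NA_real_, length(gl), ncol(values),
                dimnames = list(gl, colnames(values)))
  for (g in gl) {
    out[g, ] <- .polishSummary(values[idx[[g]], , drop = FALSE], eps, maxiter)
  }
  ann <- sampleAnnotation(x)
  GeneExperiment(out, annotation = if (nrow(ann)) ann else NULL)
}

.polishSummary <- function(block, eps = 1e-6, maxiter = 20L) {
  if (nrow(block) == 1L) return(block[1L, ])
  fit <- cpp_median_polish(block, eps, as.integer(maxiter))
  fit$overall + fit$col
}

#' Summarize a subset of a gene's probes
#'
#' Median-polish summary restricted to chosen probes of one gene — the
#' probe-subset ("exon-level") view used to check cross-hybridization:
#' when a gene's 3' probes pick up signal from a homologous transcript but
#' its 5' probes do not, summaries of the two subsets disagree on
#' differential expression.
#'
#' @param x a [ProbeExperiment-class].
#' @param gene_id the gene to summarize.
#' @param probes probe ids to keep; default all probes of the gene.
#' @inheritParams medianPolishSummarize
#' @return Named numeric vector, one summary value per sample.
#' @export
summarizeProbeSubset <- function(x, gene_id, probes = NULL,
                                 eps = 1e-6, maxiter = 20L) {
  stopifnot(is(x, "ProbeExperiment"))
  all_probes <- rownames(x)[rowData(x)$gene_id == gene_id]
  if (!length(all_probes)) stop("unknown gene: ", gene_id)
  if (is.null(probes)) probes <- all_probes
  bad <- setdiff(probes, all_probes)
  if (length(bad))
    stop("probe(s) not in gene ", gene_id, ": ", paste(bad, collapse = ", "))
  if (!length(probes)) stop("probe subset is empty")
  .polishSummary(probeValues(x)[probes, , drop = FALSE], eps, maxiter)
}
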