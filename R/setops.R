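#' Flag genes that are both significant and large
#'
#' A gene is flagged for a contrast when its raw moderated p-value is
#' strictly below \code{sig} and its absolute percent change is strictly
#' above \code{large} (so p = 0.05 or |pct| = 50 do not qualify). All
#' tables must cover the same gene universe.
#'
#' @param de named list of differential-expression tables ([runDE()]).
#' @param sig,large thresholds (defaults 0.05 and 50).
#' @return named list of character vectors of flagged gene ids.
#' @export
flagGenes <- function(de, sig = 0.05, large = 50) {
  if (sig <= 0 || large < 0) stop("thresholds must be positive")
  universe <- de[[1]]$gene_id
  for (d in de)
    if (!setequal(d$gene_id, universe))
      stop("contrast tables cover different gene universes")
  lapply(de, function(d)
    sort(d$gene_id[d$p < sig & abs(d$pct_change) > large]))
}

#' Partition flagged genes into the seven Venn regions
#'
#' Given the flagged sets of the three case-vs-control contrasts, assigns
#' every flagged gene to exactly one region: m1 = shared by all three;
#' m2 = coronal & metopic only; m3 = coronal & sagittal only; m4 = metopic
#' & sagittal only; m5/m6/m7 = unique to coronal / metopic / sagittal.
#'
#' @param coronal,metopic,sagittal character vectors of flagged gene ids.
#' @return An object of class \code{"VennPartition"}: list of the seven
#'   region sets plus \code{totals}, the per-contrast flagged counts.
#' @examples
#' v <- vennPartition(c("FGF7", "VCAM1", "SFRP4"),
#'                    c("FGF7", "VCAM1", "SFRP4"),
#'                    c("FGF7", "VCAM1", "SFRP4"))
#' lengths(v[paste0("m", 1:7)])
#' @export
vennPartition <- function(coronal, metopic, sagittal) {
  C <- unique(as.character(coronal))
  M <- unique(as.character(metopic))
  S <- unique(as.character(sagittal))
  regions <- list(
    m1 = intersect(intersect(C, M), S),
    m2 = setdiff(intersect(C, M), S),
    m3 = setdiff(intersect(C, S), M),
    m4 = setdiff(intersect(M, S), C),
    m5 = setdiff(C, union(M, S)),
    m6 = setdiff(M, union(C, S)),
    m7 = setdiff(S, union(C, M)))
  regions <- lapply(regions, sort)
  structure(c(regions,
              list(totals = c(coronal = length(C), metopic = length(M),
                              sagittal = length(S)))),
            class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition of", sum(lengths(x[paste0("m", 1:7)])), "flagged genes\n")
  for (r in paste0("m", 1:7))
    cat(sprintf("  %s: %d\n", r, length(x[[r]])))
  cat("  totals:", paste(names(x$totals), x$totals, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of one contrast's flagged genes shared with another
#'
#' @param x a \code{"VennPartition"}.
#' @param regions region names to pool (e.g. \code{c("m1", "m2")}, the
#'   genes shared by coronal and metopic).
#' @param contrast which per-contrast total to divide by.
#' @return numeric(1) shared fraction.
#' @export
sharedFraction <- function(x, regions, contrast) {
  stopifnot(inherits(x, "VennPartition"))
  sum(lengths(x[regions])) / x$totals[[contrast]]
}

#' Table of genes flagged in two contrasts, with both effect sizes
#'
#' Intersects two flagged sets and reports each gene's log2 fold change and
#' percent change under both contrasts, sorted by the first contrast's lfc
#' descending. The \code{label_*} columns use the tables' reporting format,
#' \code{"lfc (pct)"}.
#'
#' @param deA,deB differential-expression tables for the two contrasts.
#' @param flaggedA,flaggedB flagged gene ids for the two contrasts.
#' @return data.frame with \code{gene_id}, \code{lfc_a}, \code{pct_a},
#'   \code{lfc_b}, \code{pct_b}, \code{label_a}, \code{label_b}.
#' @export
sharedTable <- function(deA, deB, flaggedA, flaggedB) {
  if (!setequal(deA$gene_id, deB$gene_id))
    stop("contrast tables cover different gene universes")
  genes <- intersect(flaggedA, flaggedB)
  a <- deA[match(genes, deA$gene_id), ]
  b <- deB[match(genes, deB$gene_id), ]
  ord <- order(-a$lfc, genes)
  data.frame(gene_id = genes,
             lfc_a = a$lfc, pct_a = a$pct_reported,
             lfc_b = b$lfc, pct_b = b$pct_reported,
             label_a = formatLfcPct(a$lfc),
             label_b = formatLfcPct(b$lfc),
             row.names = NULL, stringsAsFactors = FALSE)[ord, , drop = FALSE]
}

#' @rdname lfcToPct
#' @export
formatLfcPct <- function(lfc) {
  sprintf("%.2f (%d)", lfc, roundPct(lfcToPct(lfc)))
}
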