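#' Hierarchical clustering of an expression matrix along one axis
#'
#' Agglomerative clustering for heatmap ordering: gene rows are z-scored
#' (optional), distances default to 1 - Pearson correlation, linkage to
#' average. The leaf order is made deterministic by a fixed rule applied
#' to the merge tree: at every internal node the subtree with fewer leaves
#' comes first, ties broken by the smallest member id. Zero-variance items
#' cannot be placed under correlation distance and are dropped with a
#' warning.
#'
#' @param x a [GeneExperiment-class] or numeric matrix (genes x samples).
#' @param axis cluster \code{"genes"} (rows) or \code{"samples"} (columns).
#' @param metric \code{"correlation"} (1 - Pearson) or \code{"euclidean"}.
#' @param linkage \code{"average"}, \code{"complete"} or \code{"ward"}
#'   (ward.D2).
#' @param standardize z-score gene rows before clustering.
#' @return list of class \code{"ClusterResult"}: \code{hclust} (the merge
#'   tree), \code{order} (leaf ids under the deterministic rule),
#'   \code{axis}, \code{dropped} (ids removed for zero variance).
#' @examples
#' m <- matrix(rnorm(60), 6, 10,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' cl <- hierarchicalCluster(m, axis = "genes")
#' cl$order
#' @export
hierarchicalCluster <- function(x, axis = c("genes", "samples"),
                                metric = c("correlation", "euclidean"),
                                linkage = c("average", "complete", "ward"),
                                standardize = TRUE) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- if (is(x, "GeneExperiment")) geneValues(x) else as.matrix(x)
  if (standardize) {
    sds <- apply(m, 1, stats::sd)
    keep <- sds > 0
    m <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
      sds[keep]
  }
  items <- if (axis == "genes") m else t(m)
  if (nrow(items) < 2) stop("need at least 2 items to cluster")
  dropped <- character()
  if (metric == "correlation") {
    v <- apply(items, 1, stats::sd)
    if (any(v == 0)) {
      dropped <- rownames(items)[v == 0]
      warning("dropping zero-variance item(s) under correlation distance: ",
              paste(dropped, collapse = ", "))
      items <- items[v > 0, , drop = FALSE]
    }
    d <- stats::as.dist(1 - stats::cor(t(items)))
  } else {
    d <- stats::dist(items)
  }
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  structure(list(hclust = hc,
                 order = hc$labels[.deterministicOrder(hc)],
                 axis = axis, metric = metric, linkage = linkage,
                 dropped = dropped),
            class = "ClusterResult")
}

# Leaf order from the merge tree: smaller subtree first, ties by smallest
# member label. Returns leaf indices.
.deterministicOrder <- function(hc) {
  n <- length(hc$labels)
  leaves <- function(node) {
    if (node < 0) return(-node)
    m <- hc$merge[node, ]
    c(leaves(m[1]), leaves(m[2]))
  }
  walk <- function(node) {
    if (node < 0) return(-node)
    m <- hc$merge[node, ]
    l <- leaves(m[1]); r <- leaves(m[2])
    first_l <- if (length(l) != length(r)) length(l) < length(r)
               else min(hc$labels[l]) <= min(hc$labels[r])
    if (first_l) c(walk(m[1]), walk(m[2])) else c(walk(m[2]), walk(m[1]))
  }
  walk(nrow(hc$merge))
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d %s, %s distance, %s linkage\n",
              length(x$order), x$axis, x$metric, x$linkage))
  invisible(x)
}

#' Two-dimensional clustering of a gene matrix
#'
#' Clusters genes and samples with the same settings, giving the row and
#' column orders of the conventional expression heatmap.
#'
#' @inheritParams hierarchicalCluster
#' @return list with elements \code{genes} and \code{samples}, each a
#'   \code{"ClusterResult"}.
#' @export
clusterExpression <- function(x, metric = "correlation", linkage = "average",
                              standardize = TRUE) {
  list(genes = hierarchicalCluster(x, "genes", metric, linkage, standardize),
       samples = hierarchicalCluster(x, "samples", metric, linkage, standardize))
}

#' Serializable merge-list form of a clustering
#'
#' @param x a \code{"ClusterResult"}.
#' @return list with \code{labels}, \code{order} and \code{merges}, the
#'   latter a list of \code{(a, b, height)} steps where negative entries
#'   index leaves and positive entries earlier merges (the \code{hclust}
#'   convention), suitable for JSON export.
#' @export
linkageList <- function(x) {
  stopifnot(inherits(x, "ClusterResult"))
  hc <- x$hclust
  list(labels = hc$labels, order = x$order,
       merges = lapply(seq_len(nrow(hc$merge)), function(i)
         list(a = hc$merge[i, 1], b = hc$merge[i, 2],
              height = hc$height[i])))
}
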