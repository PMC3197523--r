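#' Gene-set collection with a background universe
#'
#' Members outside the universe are dropped, then sets outside the size
#' window are removed (conventional guard against tiny or catch-all sets).
#'
#' @param sets named list of character vectors (gene ids per set).
#' @param universe background gene ids (e.g. all genes on the platform).
#' @param min_size,max_size retained set-size window after intersection.
#' @return list of class \code{"GeneSetCollection"} with \code{sets} and
#'   \code{universe}.
#' @export
geneSetCollection <- function(sets, universe, min_size = 2, max_size = Inf) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  sets <- sets[lengths(sets) >= min_size & lengths(sets) <= max_size]
  structure(list(sets = sets, universe = universe),
            class = "GeneSetCollection")
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then member gene
#' ids, one set per line.
#'
#' @param path GMT file.
#' @return named list of character vectors (descriptions in the
#'   \code{"description"} attribute of each set).
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) {
    s <- unique(f[-(1:2)])
    attr(s, "description") <- f[2]
    s
  })
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    d <- attr(sets[[n]], "description")
    paste(c(n, if (is.null(d)) "na" else d, sets[[n]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' For each set, tests whether the query list overlaps it more than
#' expected by chance with a one-sided Fisher exact test on the 2x2 table
#' (overlap, query-only, set-only, rest) — equivalently the hypergeometric
#' upper tail P(X >= overlap). \code{mode = "ease"} applies the
#' conservative EASE variant: one success is removed from the overlap cell
#' before computing the tail, so EASE p >= Fisher p. P-values are BH
#' adjusted across sets. Query genes outside the universe are dropped with
#' a warning.
#'
#' @param query character vector of gene ids (e.g. a top-GIC list).
#' @param collection a [geneSetCollection()], or a named list of sets
#'   (then \code{universe} must be given).
#' @param mode \code{"fisher"} or \code{"ease"}.
#' @param universe background used when \code{collection} is a plain list.
#' @return data.frame sorted by p: \code{set_name}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size}, \code{p},
#'   \code{p_adj}.
#' @examples
#' coll <- geneSetCollection(list(path1 = c("g1", "g2", "g3")),
#'                           universe = paste0("g", 1:100))
#' overRepresentation(c("g1", "g2", "g10"), coll)
#' @export
overRepresentation <- function(query, collection, mode = c("fisher", "ease"),
                               universe = NULL) {
  mode <- match.arg(mode)
  if (!inherits(collection, "GeneSetCollection")) {
    if (is.null(universe)) stop("a universe is required with a plain set list")
    collection <- geneSetCollection(collection, universe)
  }
  query <- unique(as.character(query))
  if (!length(query)) stop("query is empty")
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the universe")
    query <- setdiff(query, outside)
    if (!length(query)) stop("no query genes remain inside the universe")
  }
  N <- length(collection$universe)
  n <- length(query)
  res <- lapply(sort(names(collection$sets)), function(sn) {
    s <- collection$sets[[sn]]
    k <- length(intersect(query, s))
    K <- length(s)
    kk <- if (mode == "ease") max(k - 1L, 0L) else k
    # upper tail P(X >= kk) for X ~ Hypergeom(K, N - K, n)
    p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = sn, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bhAdjust(res$p)
  res[order(res$p, res$set_name), , drop = FALSE]
}
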