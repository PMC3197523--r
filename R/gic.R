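#' Gene Information Content of one probe block
#'
#' The GIC of a gene is the fraction of probe-level variance explained by
#' the first singular value of its probe x sample block: rows (probes) are
#' mean-centered and the statistic is \eqn{s_1^2 / \sum_i s_i^2} from the
#' SVD of the centered block. Probes that move together across samples give
#' a near rank-1 block and a GIC near 1; incoherent probes spread the
#' spectrum and pull the GIC toward 1/min(p, n-1).
#'
#' Degenerate conventions: a single-probe block scores 1.0 (one nonzero
#' singular value by construction) and an all-constant block scores 0.0;
#' both are flagged by [computeGIC()].
#'
#' @param block numeric matrix, probes x samples (>= 2 samples).
#' @return numeric(1) in [0, 1].
#' @examples
#' gicScore(rbind(1:6, 2 * (1:6)))        # rank-1: 1.0
#' gicScore(rbind(c(-1, 1, 0), c(0, 0, 0) + c(1, 1, -2) / sqrt(3)))
#' @export
gicScore <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) < 2) stop("GIC needs at least 2 samples")
  if (nrow(block) == 1L) {
    return(if (stats::var(block[1, ]) > 0) 1.0 else 0.0)
  }
  centered <- block - rowMeans(block)
  total <- sum(centered^2)
  if (total == 0) return(0.0)
  d <- svd(centered, nu = 0, nv = 0)$d
  d[1]^2 / sum(d^2)
}

#' Per-gene GIC scores for a probe matrix
#'
#' @param x a [ProbeExperiment-class] (quantile-normalized probe data; the
#'   statistic is taken on pre-summarization probe values).
#' @return data.frame with \code{gene_id}, \code{gic}, \code{n_probes},
#'   \code{single_probe} and \code{degenerate} (zero total variance) flags,
#'   genes in first-appearance order.
#' @export
computeGIC <- function(x) {
  stopifnot(is(x, "ProbeExperiment"))
  values <- probeValues(x)
  gene <- rowData(x)$gene_id
  gl <- unique(gene)
  idx <- split(seq_len(nrow(values)), factor(gene, levels = gl))
  centered <- values - rowMeans(values)
  sizes <- lengths(idx)
  rows0 <- unlist(idx, use.names = FALSE) - 1L
  gic <- cpp_gic_blocks(centered, rows0, as.integer(sizes))
  ss <- rowSums(centered^2)
  tot <- vapply(idx, function(i) sum(ss[i]), 0)
  data.frame(gene_id = gl, gic = gic, n_probes = as.integer(sizes),
             single_probe = sizes == 1L, degenerate = tot == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation null and cutoff for GIC scores
#'
#' Shuffles the probe-to-gene map uniformly at random while preserving
#' every gene's probe count, recomputes the GIC of each permuted probe set,
#' pools the scores over all permutations, and takes their \code{probability}
#' quantile (default the 99th percentile, linear interpolation between
#' order statistics) as the significance cutoff. Observed genes must beat
#' this to be considered coherent beyond chance.
#'
#' @inheritParams computeGIC
#' @param nPermutations number of map permutations (>= 1; 1000 is the
#'   conventional choice).
#' @param seed integer seed for the permutations.
#' @param probability null quantile defining the cutoff.
#' @param identity if TRUE, use the identity permutation every round (test
#'   hook: permuted scores then equal observed scores).
#' @return list with \code{cutoff}, \code{permuted_scores} (pooled),
#'   \code{n_permutations}, \code{probability}, \code{seed}.
#' @export
permutationCutoff <- function(x, nPermutations = 1000L, seed = 1L,
                              probability = 0.99, identity = FALSE) {
  stopifnot(is(x, "ProbeExperiment"))
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  values <- probeValues(x)
  gene <- rowData(x)$gene_id
  gl <- unique(gene)
  if (length(gl) < 2) stop("permutation null needs at least 2 genes")
  idx <- split(seq_len(nrow(values)), factor(gene, levels = gl))
  sizes <- as.integer(lengths(idx))
  centered <- values - rowMeans(values)
  np <- nrow(values)
  set.seed(seed)
  pooled <- vector("list", nPermutations)
  for (b in seq_len(nPermutations)) {
    ord <- if (identity) unlist(idx, use.names = FALSE) else sample.int(np)
    pooled[[b]] <- cpp_gic_blocks(centered, ord - 1L, sizes)
  }
  pooled <- unlist(pooled, use.names = FALSE)
  list(cutoff = unname(stats::quantile(pooled, probability, type = 7)),
       permuted_scores = pooled,
       n_permutations = as.integer(nPermutations),
       probability = probability, seed = as.integer(seed))
}

#' GIC screening: scores, permutation cutoff, ranks
#'
#' Runs [computeGIC()] and [permutationCutoff()] on the same probe matrix
#' and assembles a [GicResult-class]: genes ranked by GIC (descending, ties
#' by gene id) with a pass flag for \code{gic > cutoff}.
#'
#' @inheritParams permutationCutoff
#' @return A [GicResult-class].
#' @export
gicAnalysis <- function(x, nPermutations = 1000L, seed = 1L,
                        probability = 0.99) {
  obs <- computeGIC(x)
  null <- permutationCutoff(x, nPermutations = nPermutations, seed = seed,
                            probability = probability)
  ord <- order(-obs$gic, obs$gene_id)
  rank <- integer(nrow(obs))
  rank[ord] <- seq_len(nrow(obs))
  sc <- S4Vectors::DataFrame(obs, rank = rank,
                             passes_cutoff = obs$gic > null$cutoff)
  new("GicResult", scores = sc, cutoff = null$cutoff,
      nullScores = null$permuted_scores,
      nPermutations = null$n_permutations,
      probability = probability, seed = as.integer(seed))
}

#' Select the top-K coherent genes
#'
#' Drops genes failing the permutation cutoff (and, by default,
#' single-probe genes, whose coherence is vacuous), sorts the remainder by
#' GIC descending with ties broken by lexicographic gene id, and keeps the
#' top \code{k} (the screening step that feeds clustering and differential
#' expression; 2000 is the conventional list size). If fewer than \code{k}
#' genes pass, all passing genes are returned with a warning.
#'
#' @param result a [GicResult-class].
#' @param k number of genes to retain (> 0).
#' @param excludeSingleProbe drop single-probe genes first.
#' @return character vector of selected gene ids, highest GIC first.
#' @export
rankAndSelect <- function(result, k, excludeSingleProbe = TRUE) {
  stopifnot(is(result, "GicResult"))
  if (k <= 0) stop("k must be positive")
  sc <- as.data.frame(result@scores)
  keep <- sc$passes_cutoff
  if (excludeSingleProbe) keep <- keep & !sc$single_probe
  sc <- sc[keep, , drop = FALSE]
  sc <- sc[order(-sc$gic, sc$gene_id), , drop = FALSE]
  if (k > nrow(sc)) {
    warning("only ", nrow(sc), " genes pass the cutoff; returning all of them")
    k <- nrow(sc)
  }
  sc$gene_id[seq_len(k)]
}
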