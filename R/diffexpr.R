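#' Default contrast set for the four-group design
#'
#' The three case-vs-control contrasts, the pooled all-cases-vs-control
#' contrast, and the three case-vs-case contrasts. The pooled contrast
#' compares the sample-size-weighted average of the three case-group means
#' against control. Contrasts are written \code{"A:B"} meaning A minus B.
#'
#' @return character vector of contrast specifications.
#' @export
deContrasts <- function() {
  c("coronal:control", "metopic:control", "sagittal:control", "all:control",
    "coronal:metopic", "coronal:sagittal", "metopic:sagittal")
}

.designMatrix <- function(annotation, batch = c("gls", "fixed")) {
  batch <- match.arg(batch)
  need <- c("group", "age_months", "sex")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"control" %in% annotation$group) stop("control group is absent")
  if (anyNA(annotation[need])) stop("annotation has incomplete covariates")
  f <- if (batch == "fixed" && "batch" %in% names(annotation) &&
           length(unique(annotation$batch)) > 1)
    ~ 0 + group + age_months + sex + batch else ~ 0 + group + age_months + sex
  design <- stats::model.matrix(f, data = annotation)
  colnames(design) <- sub("^group", "", colnames(design))
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1L):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  design
}

.contrastMatrix <- function(contrasts, design, annotation) {
  groups <- c("control", "sagittal", "coronal", "metopic")
  cm <- matrix(0, ncol(design), length(contrasts),
               dimnames = list(colnames(design),
                               gsub(":", "_", contrasts, fixed = TRUE)))
  ncase <- table(factor(annotation$group, levels = groups))[-1]
  for (j in seq_along(contrasts)) {
    ab <- strsplit(contrasts[j], ":", fixed = TRUE)[[1]]
    if (length(ab) != 2) stop("malformed contrast: ", contrasts[j])
    for (s in c(1, -1)) {
      g <- ab[if (s == 1) 1 else 2]
      if (g == "all") {
        w <- ncase / sum(ncase)
        cm[names(w), j] <- cm[names(w), j] + s * w
      } else {
        if (!g %in% rownames(cm)) stop("unknown group in contrast: ", g)
        cm[g, j] <- cm[g, j] + s
      }
    }
  }
  cm
}

#' Fit per-gene linear models with covariate adjustment and batch blocking
#'
#' Fits, for every gene, expression ~ group means + age + sex, with the
#' processing batch handled either as a random effect — a consensus
#' intra-batch correlation estimated across genes, then per-gene
#' generalized least squares (\code{batch = "gls"}, the
#' \code{limma::duplicateCorrelation} approach) — or as fixed-effect
#' columns (\code{batch = "fixed"}). On balanced designs the two modes
#' agree closely.
#'
#' @param x a [GeneExperiment-class].
#' @param annotation per-sample covariates; default taken from
#'   \code{colData(x)}. Needs \code{group}, \code{age_months}, \code{sex}
#'   and (for blocking) \code{batch}.
#' @param batch \code{"gls"} (default) or \code{"fixed"}; anything else
#'   disables batch handling.
#' @return list with the \code{limma} fit (\code{MArrayLM}: coefficients,
#'   unscaled standard errors, \code{sigma}, \code{df.residual}), the
#'   design matrix, the batch mode and the estimated intra-batch
#'   correlation (NA unless \code{batch = "gls"}).
#' @export
fitGeneModels <- function(x, annotation = NULL, batch = c("gls", "fixed", "none")) {
  stopifnot(is(x, "GeneExperiment"))
  batch <- match.arg(batch)
  if (is.null(annotation)) annotation <- sampleAnnotation(x)
  if (!nrow(annotation)) stop("no sample annotation available")
  annotation <- droplevels(as.data.frame(annotation))
  design <- .designMatrix(annotation, batch = if (batch == "fixed") "fixed" else "gls")
  values <- geneValues(x)
  corr <- NA_real_
  if (batch == "gls" && "batch" %in% names(annotation) &&
      length(unique(annotation$batch)) > 1) {
    dc <- limma::duplicateCorrelation(values, design, block = annotation$batch)
    corr <- dc$consensus.correlation
    fit <- limma::lmFit(values, design, block = annotation$batch,
                        correlation = corr)
  } else {
    fit <- limma::lmFit(values, design)
  }
  list(fit = fit, design = design, annotation = annotation,
       batch = batch, intrabatch_correlation = corr)
}

#' Moderated differential expression over a set of contrasts
#'
#' Applies the requested contrasts to a per-gene fit, moderates the
#' residual variances with the empirical-Bayes squeeze (see
#' [moderateVariances()]) to get moderated t-statistics, and adjusts
#' p-values per contrast with Benjamini-Hochberg. Effect sizes are
#' reported both as log2 fold change and as signed percent change
#' ([lfcToPct()]); the \code{sig} and \code{large} flags apply the strict
#' thresholds \code{p < sig} on the raw moderated p-value and
#' \code{|percent change| > large}.
#'
#' @inheritParams fitGeneModels
#' @param contrasts character vector of \code{"A:B"} contrasts
#'   (default [deContrasts()]).
#' @param sig significance threshold on the raw moderated p-value.
#' @param large percent-change magnitude threshold.
#' @return named list (one element per contrast, \code{"A_B"}) of
#'   data.frames with columns \code{gene_id}, \code{lfc}, \code{pct_change},
#'   \code{pct_reported} (integer, half away from zero), \code{t}, \code{p},
#'   \code{p_adj}, \code{sig}, \code{large}.
#' @examples
#' d <- studyDesign(n_control = 10, n_sagittal = 10, n_coronal = 10,
#'                  n_metopic = 10, seed = 7)
#' pe <- simulateStudy(d, plantedGenes(20, coherence = 0.8, seed = 7))
#' ge <- medianPolishSummarize(quantileNormalize(pe))
#' de <- runDE(ge, contrasts = "coronal:control")
#' head(de$coronal_control)
#' @export
runDE <- function(x, annotation = NULL, contrasts = deContrasts(),
                  batch = c("gls", "fixed", "none"), sig = 0.05, large = 50) {
  model <- fitGeneModels(x, annotation, batch = match.arg(batch))
  cm <- .contrastMatrix(contrasts, model$design, model$annotation)
  cfit <- limma::eBayes(limma::contrasts.fit(model$fit, cm))
  out <- lapply(colnames(cm), function(cn) {
    lfc <- cfit$coefficients[, cn]
    pct <- lfcToPct(lfc)
    p <- cfit$p.value[, cn]
    data.frame(gene_id = rownames(cfit$coefficients),
               lfc = lfc, pct_change = pct, pct_reported = roundPct(pct),
               t = cfit$t[, cn], p = p, p_adj = bhAdjust(p),
               sig = p < sig, large = abs(pct) > large,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(cm)
  out
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Shrinks gene-wise residual variances toward a common prior by fitting a
#' scaled inverse-chi-square prior \eqn{(d_0, s_0^2)} to the observed
#' variances (moment matching on log s^2) and returning the posterior
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}. Moderated t-tests
#' use \eqn{d + d_0} degrees of freedom. When the variances are
#' (essentially) identical the prior df is \code{Inf} and every posterior
#' equals the common value. Delegates to \code{limma::squeezeVar}.
#'
#' @param s2 gene-wise residual variances (>= 10 genes).
#' @param df residual degrees of freedom (scalar or per gene).
#' @return list with \code{var_post}, \code{var_prior} (\eqn{s_0^2}) and
#'   \code{df_prior} (\eqn{d_0}, possibly \code{Inf}).
#' @export
moderateVariances <- function(s2, df) {
  if (length(s2) < 10) stop("variance moderation needs at least 10 genes")
  sv <- limma::squeezeVar(s2, df)
  list(var_post = sv$var.post, var_prior = sv$var.prior,
       df_prior = sv$df.prior)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: adjusted value for the i-th order
#' statistic is \eqn{\min_{j \ge i} p_{(j)} n / j}, capped at 1, returned
#' in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Convert log2 fold change to signed percent change
#'
#' \deqn{pct = sign(lfc) (2^{|lfc|} - 1) \times 100.}
#' A doubling (lfc = 1) is +100%; a halving (lfc = -1) is -100%. The signed
#' form keeps down-regulation symmetric with up-regulation, so magnitudes
#' above 100 are possible in both directions. \code{roundPct()} applies the
#' reporting convention: round half away from zero to the nearest integer.
#'
#' @param lfc finite numeric log2 fold changes.
#' @return percent change, unrounded.
#' @examples
#' lfcToPct(1.01)          # 101.39...
#' roundPct(lfcToPct(-1.04))  # -106
#' @export
lfcToPct <- function(lfc) {
  if (!all(is.finite(lfc))) stop("log2 fold changes must be finite")
  sign(lfc) * (2^abs(lfc) - 1) * 100
}

#' @rdname lfcToPct
#' @param pct numeric percent changes.
#' @export
roundPct <- function(pct) {
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}

#' Per-contrast summary counts
#'
#' @param de a list of differential-expression tables from [runDE()].
#' @return data.frame with, per contrast, the number of genes tested, the
#'   number and percentage significant, and the number both significant
#'   and large.
#' @export
deSummary <- function(de) {
  data.frame(
    contrast = names(de),
    n_genes = vapply(de, nrow, 0L),
    n_sig = vapply(de, function(d) sum(d$sig), 0L),
    pct_sig = vapply(de, function(d) 100 * sum(d$sig) / nrow(d), 0),
    n_sig_large = vapply(de, function(d) sum(d$sig & d$large), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
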