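#' Study design for the synthetic data generator
#'
#' Describes a four-group single-suture craniosynostosis expression study:
#' group sizes, per-group age ranges (months), per-group male fractions and
#' the number of processing batches. Defaults reproduce the design of the
#' osteoblast study the package targets: 50 controls and 100 sagittal, 50
#' coronal and 49 metopic cases, with the corresponding demographic ranges.
#'
#' @param n_control,n_sagittal,n_coronal,n_metopic group sizes (>= 2 each).
#' @param age_range named list of \code{c(min, max)} ages in months per group.
#' @param male_fraction named numeric, fraction of male samples per group.
#' @param n_batches number of processing-date batches (>= 1).
#' @param seed integer seed controlling every random draw downstream.
#' @return An object of class \code{"StudyDesign"} (a validated list).
#' @examples
#' d <- studyDesign(seed = 1)
#' nrow(generateDesign(d))  # 249 samples
#' @export
studyDesign <- function(n_control = 50, n_sagittal = 100, n_coronal = 50,
                        n_metopic = 49,
                        age_range = list(control  = c(1, 120),
                                         sagittal = c(2, 28),
                                         coronal  = c(4, 24),
                                         metopic  = c(3, 19)),
                        male_fraction = c(control = 35 / 50, sagittal = 77 / 100,
                                          coronal = 18 / 50, metopic = 36 / 49),
                        n_batches = 5, seed = 1) {
  n <- c(control = n_control, sagittal = n_sagittal,
         coronal = n_coronal, metopic = n_metopic)
  if (any(n < 2)) stop("invalid design: every group needs at least 2 samples")
  grp <- names(n)
  if (!all(grp %in% names(age_range)) || !all(grp %in% names(male_fraction)))
    stop("age_range and male_fraction must name all four groups")
  for (g in grp) {
    r <- age_range[[g]]
    if (length(r) != 2 || r[1] < 1 || r[2] < r[1])
      stop("invalid age range for group ", g, " (min must be >= 1 month)")
    if (male_fraction[[g]] < 0 || male_fraction[[g]] > 1)
      stop("male_fraction for group ", g, " must lie in [0, 1]")
  }
  if (n_batches < 1) stop("n_batches must be >= 1")
  structure(list(n = n, age_range = age_range,
                 male_fraction = male_fraction,
                 n_batches = as.integer(n_batches), seed = as.integer(seed)),
            class = "StudyDesign")
}

#' Draw a sample annotation table from a study design
#'
#' One row per sample with group, age (uniform integer within the group's
#' range), sex (Bernoulli at the group's male fraction) and batch (round
#' robin over batches, emulating consecutive processing dates). The draw is
#' fully determined by \code{design$seed}.
#'
#' @param design a [studyDesign()] object.
#' @return data.frame with columns \code{sample_id}, \code{group} (factor,
#'   control first), \code{age_months}, \code{sex} (\code{"female"}/
#'   \code{"male"}) and \code{batch}.
#' @export
generateDesign <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  set.seed(design$seed)
  groups <- rep(names(design$n), design$n)
  ntot <- length(groups)
  age <- integer(ntot)
  sex <- character(ntot)
  for (g in names(design$n)) {
    i <- which(groups == g)
    r <- design$age_range[[g]]
    age[i] <- sample(seq.int(r[1], r[2]), length(i), replace = TRUE)
    sex[i] <- ifelse(stats::rbinom(length(i), 1, design$male_fraction[[g]]) == 1,
                     "male", "female")
  }
  data.frame(
    sample_id = sprintf("S%03d", seq_len(ntot)),
    group = factor(groups, levels = c("control", "sagittal", "coronal", "metopic")),
    age_months = age,
    sex = factor(sex, levels = c("female", "male")),
    batch = factor(sprintf("b%d", rep_len(seq_len(design$n_batches), ntot))),
    stringsAsFactors = FALSE)
}

#' Specify a gene for the probe-level simulator
#'
#' A planted gene couples a shared gene-level expression signal to
#' \code{n_probes} probes. \code{coherence} is the share of each probe's
#' stochastic variance driven by the shared signal (what the GIC statistic
#' estimates); \code{lfc} plants per-group log2 fold changes relative to
#' control.
#'
#' @param gene_id gene identifier (unique within a gene list).
#' @param n_probes number of probes (>= 2; 1 allowed for degenerate tests).
#' @param coherence fraction in [0, 1].
#' @param lfc named numeric of planted log2 fold changes vs control, e.g.
#'   \code{c(coronal = 1.17)}; unnamed groups get 0.
#' @param batch_sd SD (log2) of per-batch random offsets for this gene.
#' @param noise_sd total stochastic SD (log2) per probe; must be > 0.
#' @return An object of class \code{"PlantedGene"}.
#' @export
plantedGene <- function(gene_id, n_probes, coherence = 0.3, lfc = numeric(),
                        batch_sd = 0.3, noise_sd = 0.5) {
  if (coherence < 0 || coherence > 1)
    stop("coherence must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_probes < 1) stop("n_probes must be >= 1")
  full <- c(sagittal = 0, coronal = 0, metopic = 0)
  if (length(lfc)) {
    if (is.null(names(lfc)) || !all(names(lfc) %in% names(full)))
      stop("lfc must be named with case-group names")
    full[names(lfc)] <- lfc
  }
  structure(list(gene_id = as.character(gene_id),
                 n_probes = as.integer(n_probes),
                 coherence = coherence, lfc = full,
                 batch_sd = batch_sd, noise_sd = noise_sd),
            class = "PlantedGene")
}

#' Build a list of planted genes with randomized probe counts
#'
#' Probe counts are drawn uniform-integer in \code{probe_range} (default
#' 4-26, plausible for a whole-transcript array) using \code{seed}; other
#' parameters are recycled across genes.
#'
#' @param n_genes number of genes.
#' @param coherence,batch_sd,noise_sd recycled per-gene parameters.
#' @param lfc a single named lfc vector applied to all genes, or a list of
#'   per-gene lfc vectors.
#' @param probe_range integer \code{c(min, max)} probe count.
#' @param seed integer seed for the probe-count draw.
#' @return list of [plantedGene()] objects with ids \code{gene0001, ...}.
#' @export
plantedGenes <- function(n_genes, coherence = 0.3, lfc = numeric(),
                         batch_sd = 0.3, noise_sd = 0.5,
                         probe_range = c(4L, 26L), seed = 1) {
  set.seed(seed)
  np <- sample(seq.int(probe_range[1], probe_range[2]), n_genes, replace = TRUE)
  coherence <- rep_len(coherence, n_genes)
  batch_sd <- rep_len(batch_sd, n_genes)
  noise_sd <- rep_len(noise_sd, n_genes)
  if (!is.list(lfc)) lfc <- rep(list(lfc), n_genes)
  lapply(seq_len(n_genes), function(i)
    plantedGene(sprintf("gene%04d", i), np[i], coherence[i], lfc[[i]],
                batch_sd[i], noise_sd[i]))
}

#' Simulate a probe-level expression matrix
#'
#' For each gene g and sample s a latent gene-level value is drawn,
#' \deqn{z_{gs} = \mu_g + lfc_g(group_s) + \beta_{age} age_s +
#'   \beta_{sex} male_s + b_{g,batch_s} + \sqrt{c_g}\,\sigma_g u_{gs},}
#' with \eqn{u_{gs} \sim N(0,1)} and per-batch offsets
#' \eqn{b \sim N(0, batch\_sd^2)}. Probe p then reports
#' \deqn{y_{ps} = a_p z_{gs} + \sqrt{1 - c_g}\,\sigma_g \epsilon_{ps},}
#' where \eqn{a_p \sim N(1, affinity\_sd^2)} are fixed probe affinities
#' (hybridization efficiency absorbed later by median polish) and
#' \eqn{c_g} is the gene's coherence: the split puts a fraction c of each
#' probe's stochastic variance into the shared signal, so planted fold
#' changes pass through unattenuated while probe coherence is controlled.
#'
#' @param annotation sample table from [generateDesign()].
#' @param genes list of [plantedGene()] objects with distinct ids.
#' @param seed integer seed.
#' @param beta_age age effect, log2 units per month.
#' @param beta_sex male-vs-female offset, log2 units.
#' @param affinity_sd SD of probe affinities around 1; 0 gives identical
#'   probes up to noise.
#' @param baseline_range range of per-gene baseline log2 expression.
#' @return A [ProbeExperiment-class]; probes are named
#'   \code{<gene_id>_p<k>}.
#' @examples
#' ann <- generateDesign(studyDesign(n_control = 5, n_sagittal = 5,
#'                                   n_coronal = 5, n_metopic = 5, seed = 1))
#' pe <- generateProbeData(ann, plantedGenes(3, seed = 1), seed = 2)
#' dim(probeValues(pe))
#' @export
generateProbeData <- function(annotation, genes, seed,
                              beta_age = 0.002, beta_sex = 0.1,
                              affinity_sd = 0.2, baseline_range = c(4, 12)) {
  if (!nrow(annotation)) stop("annotation must be non-empty")
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("planted gene ids must be distinct")
  set.seed(seed)
  ns <- nrow(annotation)
  grp <- as.character(annotation$group)
  male <- as.numeric(annotation$sex == "male")
  batch <- as.factor(annotation$batch)
  blocks <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    baseline <- stats::runif(1, baseline_range[1], baseline_range[2])
    a <- stats::rnorm(g$n_probes, 1, affinity_sd)
    b <- stats::rnorm(nlevels(batch), 0, g$batch_sd)
    lfc <- c(control = 0, g$lfc)[grp]
    mu <- baseline + lfc + beta_age * annotation$age_months + beta_sex * male +
      b[as.integer(batch)]
    z <- mu + sqrt(g$coherence) * g$noise_sd * stats::rnorm(ns)
    eps <- matrix(stats::rnorm(g$n_probes * ns, 0,
                               sqrt(1 - g$coherence) * g$noise_sd),
                  g$n_probes, ns)
    m <- outer(a, z) + eps
    rownames(m) <- sprintf("%s_p%02d", g$gene_id, seq_len(g$n_probes))
    blocks[[k]] <- m
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- annotation$sample_id
  ProbeExperiment(values,
                  gene_id = rep(ids, vapply(genes, `[[`, 0L, "n_probes")),
                  annotation = annotation)
}

#' One-call synthetic study
#'
#' Convenience wrapper: draws the annotation from \code{design} and the
#' probe matrix from \code{genes} (seeded off \code{design$seed} so a
#' design fully determines the dataset).
#'
#' @inheritParams generateProbeData
#' @param design a [studyDesign()].
#' @param genes list of planted genes; default 200 background genes.
#' @return A [ProbeExperiment-class] with annotation in \code{colData}.
#' @export
simulateStudy <- function(design, genes = NULL, ...) {
  ann <- generateDesign(design)
  if (is.null(genes)) genes <- plantedGenes(200, seed = design$seed)
  generateProbeData(ann, genes, seed = design$seed + 1L, ...)
}

#' Read and write the tab-delimited study formats
#'
#' The on-disk layout is three tab-delimited text files: the probe matrix
#' (first column \code{probe_id}, then one column per sample), the
#' two-column probe map (\code{probe_id}, \code{gene_id}) and the sample
#' annotation (\code{sample_id}, \code{group}, \code{age_months},
#' \code{sex}, \code{batch}).
#'
#' @param x a [ProbeExperiment-class].
#' @param dir output directory (created if needed).
#' @return \code{writeStudy}: invisibly, the three file paths.
#' @export
writeStudy <- function(x, dir) {
  stopifnot(is(x, "ProbeExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("probes.tsv", "probe_map.tsv", "annotation.tsv"))
  m <- data.frame(probe_id = rownames(x), probeValues(x), check.names = FALSE)
  utils::write.table(m, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(probeGeneMap(x), paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sampleAnnotation(x), paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname writeStudy
#' @param probes,map,annotation paths to the three files (\code{annotation}
#'   may be \code{NULL}).
#' @return \code{readStudy}: a [ProbeExperiment-class].
#' @export
readStudy <- function(probes, map, annotation = NULL) {
  pm <- utils::read.delim(probes, check.names = FALSE)
  values <- as.matrix(pm[, -1, drop = FALSE])
  rownames(values) <- pm[[1]]
  pg <- utils::read.delim(map)
  idx <- match(rownames(values), pg$probe_id)
  if (anyNA(idx)) stop("probe map is missing probes from the matrix")
  ann <- if (!is.null(annotation)) utils::read.delim(annotation) else NULL
  if (!is.null(ann)) {
    need <- c("sample_id", "group", "age_months", "sex", "batch")
    miss <- setdiff(need, names(ann))
    if (length(miss))
      stop("annotation is missing required column(s): ",
           paste(miss, collapse = ", "))
    ann$group <- factor(ann$group,
                        levels = c("control", "sagittal", "coronal", "metopic"))
    ann$sex <- factor(ann$sex, levels = c("female", "male"))
    ann$batch <- factor(ann$batch)
  }
  ProbeExperiment(values, gene_id = pg$gene_id[idx], annotation = ann)
}
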