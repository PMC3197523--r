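#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Paths may be omitted
#' when a [ProbeExperiment-class] is handed to [runPipeline()] directly.
#'
#' @param probes,map,annotation paths to the tab-delimited probe matrix,
#'   probe map and sample annotation (see [writeStudy()]).
#' @param gmt optional path to a GMT gene-set file for the enrichment stage.
#' @param n_permutations GIC permutation count (1000 conventional).
#' @param top_k genes retained after GIC ranking (2000 conventional).
#' @param probability null quantile for the GIC cutoff.
#' @param seed integer seed for every stochastic stage.
#' @param contrasts contrast specifications, see [deContrasts()].
#' @param batch batch handling, \code{"gls"}, \code{"fixed"} or
#'   \code{"none"}.
#' @param sig_threshold,large_threshold significance / percent-change
#'   thresholds for flagging.
#' @param cluster_metric,cluster_linkage see [hierarchicalCluster()].
#' @param enrich_mode \code{"fisher"} or \code{"ease"}.
#' @param min_set_size,max_set_size gene-set size window.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(probes = NULL, map = NULL, annotation = NULL,
                           gmt = NULL, n_permutations = 1000L, top_k = 2000L,
                           probability = 0.99, seed = 1L,
                           contrasts = deContrasts(), batch = "gls",
                           sig_threshold = 0.05, large_threshold = 50,
                           cluster_metric = "correlation",
                           cluster_linkage = "average",
                           enrich_mode = "fisher",
                           min_set_size = 2, max_set_size = Inf) {
  if (n_permutations < 1 || top_k < 1 || sig_threshold <= 0 ||
      large_threshold < 0 || probability <= 0 || probability >= 1)
    stop("invalid pipeline thresholds")
  structure(list(probes = probes, map = map, annotation = annotation,
                 gmt = gmt, n_permutations = as.integer(n_permutations),
                 top_k = as.integer(top_k), probability = probability,
                 seed = as.integer(seed), contrasts = contrasts,
                 batch = batch, sig_threshold = sig_threshold,
                 large_threshold = large_threshold,
                 cluster_metric = cluster_metric,
                 cluster_linkage = cluster_linkage,
                 enrich_mode = enrich_mode, min_set_size = min_set_size,
                 max_set_size = max_set_size),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file whose keys are \code{pipelineConfig()} arguments.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes normalization (quantile + median polish), GIC screening with
#' the permutation cutoff, top-K selection, moderated differential
#' expression over all contrasts, significant-and-large flagging with the
#' three-way Venn partition, two-dimensional clustering of the selected
#' genes, and (when a GMT is configured) over-representation analysis.
#' All artifacts are tab-delimited or JSON text files under \code{out_dir},
#' plus a \code{manifest.json} recording parameters, seeds, per-stage row
#' counts and an md5 per output. A failing stage aborts with the stage
#' name; partial outputs are moved under \code{out_dir/failed/}.
#'
#' @param config a [pipelineConfig()] or path to its YAML form.
#' @param out_dir output directory (created).
#' @param data optional [ProbeExperiment-class]; when given the configured
#'   input paths are ignored.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(config, out_dir, data = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  fail <- function(e) {
    failed <- file.path(out_dir, "failed")
    dir.create(failed, showWarnings = FALSE)
    made <- setdiff(list.files(out_dir), "failed")
    file.rename(file.path(out_dir, made), file.path(failed, made))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  manifest <- list(package = as.character(utils::packageVersion("sutureGIC")),
                   seed = config$seed,
                   parameters = config[!vapply(config, is.null, TRUE)],
                   stages = list())
  tryCatch({
    if (is.null(data)) {
      for (p in c("probes", "map", "annotation"))
        if (is.null(config[[p]]) || !file.exists(config[[p]]))
          stop("configured input '", p, "' does not exist")
      data <- readStudy(config$probes, config$map, config$annotation)
    }
    manifest$stages$input <- list(probes = nrow(data), samples = ncol(data))

    stage <- "normalize"
    norm <- quantileNormalize(data)
    ge <- medianPolishSummarize(norm)
    gmat <- data.frame(gene_id = rownames(ge), geneValues(ge),
                       check.names = FALSE)
    utils::write.table(gmat, file.path(out_dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$normalize <- list(genes = nrow(ge))

    stage <- "gic"
    gr <- gicAnalysis(norm, nPermutations = config$n_permutations,
                      seed = config$seed, probability = config$probability)
    utils::write.table(gicScores(gr), file.path(out_dir, "gic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cutoff = gicCutoff(gr), n_permutations = gr@nPermutations,
           probability = gr@probability, seed = gr@seed),
      file.path(out_dir, "gic_null.json"), auto_unbox = TRUE, digits = NA)
    selected <- suppressWarnings(rankAndSelect(gr, config$top_k))
    writeLines(selected, file.path(out_dir, "selected_genes.txt"))
    manifest$stages$gic <- list(cutoff = gicCutoff(gr),
                                n_pass = sum(gicScores(gr)$passes_cutoff),
                                n_selected = length(selected))

    stage <- "diffexpr"
    ge_sel <- GeneExperiment(geneValues(ge)[selected, , drop = FALSE],
                             annotation = sampleAnnotation(ge))
    de <- runDE(ge_sel, contrasts = config$contrasts, batch = config$batch,
                sig = config$sig_threshold, large = config$large_threshold)
    for (cn in names(de))
      utils::write.table(de[[cn]], file.path(out_dir, paste0("de_", cn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$diffexpr <-
      list(contrasts = names(de),
           n_sig = vapply(de, function(d) sum(d$sig), 0L))

    stage <- "setops"
    cc <- c("coronal_control", "metopic_control", "sagittal_control")
    if (all(cc %in% names(de))) {
      fl <- flagGenes(de[cc], sig = config$sig_threshold,
                      large = config$large_threshold)
      venn <- vennPartition(fl$coronal_control, fl$metopic_control,
                            fl$sagittal_control)
      jsonlite::write_json(venn[paste0("m", 1:7)],
                           file.path(out_dir, "venn.json"))
      manifest$stages$setops <- list(flagged = venn$totals,
                                     regions = lengths(venn[paste0("m", 1:7)]))
    }

    stage <- "cluster"
    cl <- clusterExpression(ge_sel, metric = config$cluster_metric,
                            linkage = config$cluster_linkage)
    writeLines(cl$genes$order, file.path(out_dir, "gene_order.txt"))
    writeLines(cl$samples$order, file.path(out_dir, "sample_order.txt"))
    jsonlite::write_json(list(genes = linkageList(cl$genes),
                              samples = linkageList(cl$samples)),
                         file.path(out_dir, "cluster.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$cluster <- list(genes = length(cl$genes$order),
                                    samples = length(cl$samples$order))

    stage <- "enrich"
    if (!is.null(config$gmt)) {
      coll <- geneSetCollection(readGMT(config$gmt),
                                universe = rownames(ge),
                                min_size = config$min_set_size,
                                max_size = config$max_set_size)
      enr <- overRepresentation(selected, coll, mode = config$enrich_mode)
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$enrich <- list(n_sets = nrow(enr),
                                     n_sig = sum(enr$p < 0.01))
    }

    stage <- "manifest"
    outputs <- setdiff(list.files(out_dir), c("failed", "manifest.json"))
    manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, outputs)))
    names(manifest$outputs) <- outputs
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = fail)
  invisible(manifest)
}
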