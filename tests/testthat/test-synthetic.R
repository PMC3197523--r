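test_that("design tables reproduce the study layout and are deterministic", {
  d <- studyDesign(seed = 42)
  ann <- generateDesign(d)
  expect_equal(nrow(ann), 249)  # 199 cases + 50 controls
  expect_equal(as.vector(table(ann$group)[c("control", "sagittal", "coronal",
                                            "metopic")]),
               c(50L, 100L, 50L, 49L))
  for (g in names(d$n)) {
    a <- ann$age_months[ann$group == g]
    expect_true(all(a >= d$age_range[[g]][1] & a <= d$age_range[[g]][2]))
  }
  expect_identical(ann, generateDesign(studyDesign(seed = 42)))
  expect_false(identical(ann, generateDesign(studyDesign(seed = 43))))
  one <- generateDesign(studyDesign(n_batches = 1, seed = 1))
  expect_equal(length(unique(one$batch)), 1L)
})

test_that("invalid designs and gene parameters are rejected", {
  expect_error(studyDesign(n_coronal = 0), "at least 2")
  expect_error(studyDesign(age_range = list(control = c(0, 10),
                                            sagittal = c(2, 28),
                                            coronal = c(4, 24),
                                            metopic = c(3, 19))),
               "invalid age range")
  expect_error(studyDesign(n_batches = 0), "n_batches")
  expect_error(plantedGene("g", 4, coherence = 1.2), "coherence")
  expect_error(plantedGene("g", 4, noise_sd = 0), "noise_sd")
  expect_error(generateProbeData(generateDesign(smallDesign()),
                                 list(plantedGene("g", 4),
                                      plantedGene("g", 5)), seed = 1),
               "distinct")
})

test_that("probe data generation is deterministic and respects the map", {
  ann <- generateDesign(smallDesign(seed = 3))
  genes <- plantedGenes(8, seed = 3)
  a <- generateProbeData(ann, genes, seed = 7)
  b <- generateProbeData(ann, genes, seed = 7)
  expect_identical(probeValues(a), probeValues(b))
  expect_equal(nrow(a), sum(vapply(genes, `[[`, 0L, "n_probes")))
  expect_equal(unique(probeGeneMap(a)$gene_id),
               vapply(genes, `[[`, "", "gene_id"))
})

test_that("the noiseless coherent limit plants an exact fold change", {
  # coherence = 1 and vanishing noise: the coronal-vs-control probe-mean
  # difference must equal the planted 1 log2 unit exactly (affinities off)
  ann <- generateDesign(smallDesign(n = 10, seed = 5))
  g <- plantedGene("g1", 6, coherence = 1, lfc = c(coronal = 1),
                   batch_sd = 0, noise_sd = 1e-9)
  pe <- generateProbeData(ann, list(g), seed = 1, beta_age = 0, beta_sex = 0,
                          affinity_sd = 0)
  v <- probeValues(pe)
  grp <- sampleAnnotation(pe)$group
  diff <- mean(v[, grp == "coronal"]) - mean(v[, grp == "control"])
  expect_equal(diff, 1, tolerance = 1e-6)
})

test_that("a zero-coherence gene scores like unrelated probes", {
  # oracle: empirical GIC distribution over many random-probe genes of the
  # same block size
  n <- 40
  set.seed(21)
  null_gic <- replicate(2000, gicOracle(matrix(rnorm(6 * n), 6, n)))
  ann <- generateDesign(studyDesign(n_control = 10, n_sagittal = 10,
                                    n_coronal = 10, n_metopic = 10, seed = 2))
  genes <- lapply(1:60, function(i)
    plantedGene(sprintf("g%02d", i), 6, coherence = 0, batch_sd = 0))
  pe <- generateProbeData(ann, genes, seed = 3, beta_age = 0, beta_sex = 0)
  gic <- computeGIC(pe)$gic
  # same location within Monte Carlo error of both estimates
  expect_lt(abs(mean(gic) - mean(null_gic)),
            4 * sqrt(var(null_gic) / 60 + var(null_gic) / 2000))
})

test_that("mean GIC increases strictly with the coherence parameter", {
  ann <- generateDesign(studyDesign(n_control = 25, n_sagittal = 25,
                                    n_coronal = 25, n_metopic = 25, seed = 5))
  means <- vapply(c(0.1, 0.5, 0.9), function(co) {
    pe <- generateProbeData(ann, plantedGenes(40, coherence = co, seed = 6),
                            seed = 7)
    mean(computeGIC(quantileNormalize(pe))$gic)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("study files round-trip through the tab-delimited formats", {
  ann <- generateDesign(smallDesign(seed = 8))
  pe <- generateProbeData(ann, plantedGenes(4, seed = 8), seed = 9)
  dir <- withr::local_tempdir()
  writeStudy(pe, dir)
  back <- readStudy(file.path(dir, "probes.tsv"),
                    file.path(dir, "probe_map.tsv"),
                    file.path(dir, "annotation.tsv"))
  expect_equal(probeValues(back), probeValues(pe), tolerance = 1e-12)
  expect_identical(probeGeneMap(back), probeGeneMap(pe))
  expect_equal(sampleAnnotation(back)$group, sampleAnnotation(pe)$group)
})
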