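test_that("quantile normalization matches the hand-computed reference", {
  m <- cbind(a = c(1, 2, 3), b = c(3, 4, 5))
  out <- quantileNormalize(m)
  expect_equal(unname(out), cbind(c(2, 3, 4), c(2, 3, 4)))
  # order within columns is preserved
  m2 <- cbind(a = c(3, 1, 2), b = c(5, 3, 4))
  expect_equal(unname(quantileNormalize(m2)), cbind(c(4, 2, 3), c(4, 2, 3)))
})

test_that("quantile normalization is a fixed point on identical columns and idempotent", {
  set.seed(1)
  col <- rnorm(50)
  same <- cbind(col, col, col)
  expect_equal(quantileNormalize(same), same, ignore_attr = TRUE)
  m <- matrix(rnorm(200), 40, 5)
  once <- quantileNormalize(m)
  expect_equal(quantileNormalize(once), once)
  expect_equal(diff(range(colMeans(once))), 0, tolerance = 1e-12)
})

test_that("quantile normalization handles ties by rank averaging and rejects bad input", {
  m <- cbind(c(1, 1, 2), c(10, 20, 30))
  out <- quantileNormalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(out[1, 1], mean(ref[1:2]))  # tied values share averaged refs
  expect_equal(out[1, 1], out[2, 1])
  expect_error(quantileNormalize(cbind(c(1, NA), c(1, 2))), "non-finite")
  expect_error(quantileNormalize(matrix(1:3)), "at least 2")
})

test_that("median polish summarization agrees with the classic algorithm", {
  set.seed(4)
  for (dims in list(c(3, 4), c(7, 10), c(12, 30))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    mp <- stats::medpolish(x, eps = 1e-6, maxiter = 20, trace.iter = FALSE)
    expect_equal(sutureGIC:::.polishSummary(x), mp$overall + mp$col,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("median polish absorbs probe effects and resists an outlier", {
  # purely additive matrix: sample effects recovered exactly
  probe_eff <- c(0, 1, -2)
  sample_eff <- c(0, 2, 4, 6)
  x <- outer(probe_eff, rep(1, 4)) + outer(rep(1, 3), sample_eff) + 5
  s <- sutureGIC:::.polishSummary(x)
  expect_equal(diff(s), diff(sample_eff), tolerance = 1e-12)
  # probe-effect-only matrix: all samples identical
  x2 <- outer(probe_eff, rep(1, 4))
  expect_equal(diff(sutureGIC:::.polishSummary(x2)), rep(0, 3))
  # one corrupted cell leaves the additive structure untouched
  x_bad <- x
  x_bad[2, 3] <- x_bad[2, 3] + 100
  expect_equal(diff(sutureGIC:::.polishSummary(x_bad)), diff(sample_eff),
               tolerance = 1e-12)
})

test_that("gene summaries are invariant to probe row order and handle single probes", {
  ann <- generateDesign(smallDesign(seed = 2))
  pe <- generateProbeData(ann, list(plantedGene("gA", 5),
                                    plantedGene("gB", 1),
                                    plantedGene("gC", 3)), seed = 3)
  ge <- medianPolishSummarize(pe)
  # single-probe gene passes through
  expect_equal(geneValues(ge)["gB", ], probeValues(pe)["gB_p01", ])
  # shuffle probe rows within the matrix; gene order and values unchanged
  set.seed(1)
  perm <- sample(nrow(pe))
  pe2 <- ProbeExperiment(probeValues(pe)[perm, ],
                         gene_id = probeGeneMap(pe)$gene_id[perm],
                         annotation = sampleAnnotation(pe))
  ge2 <- medianPolishSummarize(pe2)
  expect_equal(geneValues(ge2)[rownames(ge), ], geneValues(ge))
})

test_that("probe-subset summaries expose cross-hybridization", {
  ann <- generateDesign(smallDesign(n = 12, seed = 6))
  # a gene whose 3' half carries a planted change while the 5' half is flat:
  # build it from two planted genes and splice their probes together
  hot <- plantedGene("hot", 3, coherence = 0.9, lfc = c(coronal = 1.5),
                     batch_sd = 0, noise_sd = 0.3)
  cold <- plantedGene("cold", 3, coherence = 0.9, batch_sd = 0,
                      noise_sd = 0.3)
  pe0 <- generateProbeData(ann, list(hot, cold), seed = 11,
                           beta_age = 0, beta_sex = 0, affinity_sd = 0)
  v <- probeValues(pe0)
  rownames(v) <- sprintf("chim_p%02d", 1:6)
  pe <- ProbeExperiment(v, gene_id = rep("chim", 6), annotation = ann)

  full <- summarizeProbeSubset(pe, "chim")
  expect_equal(full, summarizeProbeSubset(pe, "chim", rownames(v)))
  one <- summarizeProbeSubset(pe, "chim", "chim_p01")
  expect_equal(one, v["chim_p01", ])

  grp <- ann$group
  delta <- function(s) mean(s[grp == "coronal"]) - mean(s[grp == "control"])
  s3 <- summarizeProbeSubset(pe, "chim", sprintf("chim_p%02d", 1:3))
  s5 <- summarizeProbeSubset(pe, "chim", sprintf("chim_p%02d", 4:6))
  expect_gt(delta(s3), 1)      # 3' subset carries the planted change
  expect_lt(abs(delta(s5)), 0.3)  # 5' subset does not
  expect_lt(stats::t.test(s5[grp == "coronal"], s5[grp == "control"])$p.value,
            1) # well-defined
  expect_lt(stats::t.test(s3[grp == "coronal"], s3[grp == "control"])$p.value,
            0.05)

  expect_error(summarizeProbeSubset(pe, "chim", "nope"), "not in gene")
  expect_error(summarizeProbeSubset(pe, "ghost"), "unknown gene")
})
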