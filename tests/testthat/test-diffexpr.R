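test_that("a noiseless planted fold change is recovered to numerical precision", {
  ann <- generateDesign(smallDesign(n = 8, seed = 1))
  g <- plantedGene("g1", 4, coherence = 1, lfc = c(coronal = 1.17),
                   batch_sd = 0, noise_sd = 1e-9)
  gs <- c(list(g), lapply(2:12, function(i)
    plantedGene(paste0("flat", i), 4, coherence = 1, batch_sd = 0,
                noise_sd = 1e-9)))
  pe <- generateProbeData(ann, gs, seed = 2, beta_age = 0, beta_sex = 0,
                          affinity_sd = 0)
  ge <- medianPolishSummarize(pe)
  de <- runDE(ge, contrasts = "coronal:control", batch = "none")
  expect_equal(de$coronal_control$lfc[1], 1.17, tolerance = 1e-7)
})

test_that("contrasts are antisymmetric and the pooled contrast weights cases by size", {
  ann <- generateDesign(studyDesign(seed = 2))
  set.seed(5)
  G <- matrix(rnorm(30 * 249), 30, 249,
              dimnames = list(sprintf("g%02d", 1:30), ann$sample_id))
  ge <- GeneExperiment(G, annotation = ann)
  de <- runDE(ge, contrasts = c("coronal:metopic", "metopic:coronal",
                                "all:control", "coronal:control",
                                "metopic:control", "sagittal:control"),
              batch = "none")
  expect_equal(de$coronal_metopic$lfc, -de$metopic_coronal$lfc)
  w <- c(sagittal = 100, coronal = 50, metopic = 49) / 199
  pooled <- w["coronal"] * de$coronal_control$lfc +
    w["metopic"] * de$metopic_control$lfc +
    w["sagittal"] * de$sagittal_control$lfc
  expect_equal(de$all_control$lfc, unname(pooled), tolerance = 1e-12)
})

test_that("permuting group labels empties the signal", {
  ann <- generateDesign(smallDesign(n = 12, seed = 3))
  pe <- simulateStudy(smallDesign(n = 12, seed = 3),
                      plantedGenes(40, coherence = 0.5,
                                   lfc = c(coronal = 1.5), seed = 3))
  ge <- medianPolishSummarize(quantileNormalize(pe))
  ann2 <- sampleAnnotation(ge)
  set.seed(7)
  ann2$group <- sample(ann2$group)
  de <- runDE(ge, annotation = ann2, contrasts = "coronal:control",
              batch = "none")
  # with labels broken, estimates sit within 3 moderated SEs of zero
  expect_gt(mean(abs(de$coronal_control$t) < 3), 0.95)
  expect_lt(mean(abs(de$coronal_control$lfc)), 0.2)
})

test_that("age adjustment removes the planted confounding the naive fit keeps", {
  # cases drawn old, controls young, strong age effect, no group effect
  d <- studyDesign(n_control = 30, n_sagittal = 2, n_coronal = 30,
                   n_metopic = 2,
                   age_range = list(control = c(1, 12), sagittal = c(2, 28),
                                    coronal = c(60, 120), metopic = c(3, 19)),
                   seed = 11)
  ann <- generateDesign(d)
  beta_age <- 0.02
  genes <- plantedGenes(15, coherence = 1, noise_sd = 1e-6, batch_sd = 0,
                        seed = 11)
  pe <- generateProbeData(ann, genes, seed = 12, beta_age = beta_age,
                          beta_sex = 0, affinity_sd = 0)
  ge <- medianPolishSummarize(pe)
  de <- runDE(ge, contrasts = "coronal:control", batch = "none")
  expect_lt(max(abs(de$coronal_control$lfc)), 1e-4)
  # oracle: omitted-variable bias = beta_age * (mean case age - mean control age)
  bias <- beta_age * (mean(ann$age_months[ann$group == "coronal"]) -
                        mean(ann$age_months[ann$group == "control"]))
  naive <- apply(geneValues(ge), 1, function(y) {
    keep <- ann$group %in% c("coronal", "control")
    unname(coef(lm(y[keep] ~ (ann$group == "coronal")[keep]))[2])
  })
  expect_equal(mean(naive), bias, tolerance = 0.05 * abs(bias) + 1e-6)
})

test_that("random-effect and fixed-effect batch handling agree on balanced designs", {
  d <- smallDesign(n = 12, n_batches = 3, seed = 13)
  pe <- simulateStudy(d, plantedGenes(30, coherence = 0.6,
                                      lfc = c(coronal = 1), seed = 13))
  ge <- medianPolishSummarize(quantileNormalize(pe))
  gls <- runDE(ge, contrasts = "coronal:control", batch = "gls")
  fixed <- runDE(ge, contrasts = "coronal:control", batch = "fixed")
  expect_gt(cor(gls$coronal_control$lfc, fixed$coronal_control$lfc), 0.99)
  expect_lt(mean(abs(gls$coronal_control$lfc - fixed$coronal_control$lfc)),
            0.05)
})

test_that("degenerate designs fail loudly with the offending columns", {
  ann <- generateDesign(smallDesign(seed = 17))
  G <- matrix(rnorm(5 * nrow(ann)), 5, nrow(ann),
              dimnames = list(paste0("g", 1:5), ann$sample_id))
  ge <- GeneExperiment(G, annotation = ann)
  ann_bad <- sampleAnnotation(ge)
  ann_bad$age_months <- 7  # constant column aliases the intercept span
  expect_error(runDE(ge, annotation = ann_bad, batch = "none"),
               "rank deficient.*age_months")
  ann_noctl <- sampleAnnotation(ge)
  ann_noctl$group[ann_noctl$group == "control"] <- "sagittal"
  expect_error(runDE(ge, annotation = droplevels(ann_noctl), batch = "none"),
               "control group")
  expect_error(runDE(ge, contrasts = "coronal:martian", batch = "none"),
               "unknown group")
})

test_that("variance moderation recovers planted prior hyperparameters", {
  # simulate gene variances from a scaled inverse-chi-square prior
  set.seed(11)
  d0 <- 4; s02 <- 0.25
  s2 <- s02 * d0 / rchisq(5000, df = d0)
  mv <- moderateVariances(s2, df = 40)
  expect_lt(abs(mv$df_prior - d0), 1)
  expect_lt(abs(mv$var_prior - s02) / s02, 0.10)
  # posterior is the df-weighted compromise
  expect_equal(mv$var_post,
               (mv$df_prior * mv$var_prior + 40 * s2) / (mv$df_prior + 40),
               tolerance = 1e-10)
})

test_that("identical variances yield an infinite prior and a common posterior", {
  mv <- moderateVariances(rep(0.3, 50), df = 10)
  expect_true(is.infinite(mv$df_prior))
  expect_equal(mv$var_post, rep(0.3, 50))
  expect_error(moderateVariances(c(0.1, 0.2), df = 4), "at least 10")
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(100)
  # independent oracle: min over j >= i of p_(j) * n / j, mapped back
  o <- order(p)
  expected <- pmin(rev(cummin(rev(p[o] * length(p) / seq_along(p)))), 1)
  expect_equal(bhAdjust(p)[o], expected)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("percent change transforms and rounds as reported", {
  expect_equal(lfcToPct(0), 0)
  expect_equal(roundPct(lfcToPct(1.01)), 101L)
  expect_equal(roundPct(lfcToPct(-1.04)), -106L)
  expect_equal(roundPct(lfcToPct(1.67)), 218L)
  # signed symmetry and half-away-from-zero rounding
  set.seed(5)
  x <- rnorm(50)
  expect_equal(lfcToPct(-x), -lfcToPct(x))
  expect_equal(roundPct(c(0.5, -0.5, 1.5, -1.5)), c(1L, -1L, 2L, -2L))
  expect_error(lfcToPct(Inf), "finite")
})
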