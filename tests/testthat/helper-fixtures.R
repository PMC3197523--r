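# Small fixtures built in code.

# probe matrix with iid Gaussian values and a given probe-set size profile
iidProbeExperiment <- function(n_genes, n_samples, probe_range = c(4L, 26L),
                               seed = 1) {
  set.seed(seed)
  sizes <- sample(seq.int(probe_range[1], probe_range[2]), n_genes,
                  replace = TRUE)
  np <- sum(sizes)
  values <- matrix(rnorm(np * n_samples), np, n_samples,
                   dimnames = list(sprintf("p%05d", seq_len(np)),
                                   sprintf("s%03d", seq_len(n_samples))))
  ProbeExperiment(values, gene_id = rep(sprintf("g%04d", seq_len(n_genes)),
                                        sizes))
}

# balanced two-batch four-group design, small
smallDesign <- function(n = 6, n_batches = 2, seed = 1) {
  studyDesign(n_control = n, n_sagittal = n, n_coronal = n, n_metopic = n,
              n_batches = n_batches, seed = seed)
}

# independent GIC oracle: eigendecomposition of the centered block's Gram
# matrix (never touches the package's SVD path)
gicOracle <- function(block) {
  centered <- block - rowMeans(block)
  ev <- eigen(centered %*% t(centered), symmetric = TRUE,
              only.values = TRUE)$values
  max(ev) / sum(ev)
}

# minimal DE-like table for set-operation tests
fakeDeTable <- function(gene_id, lfc, p) {
  pct <- lfcToPct(lfc)
  data.frame(gene_id = gene_id, lfc = lfc, pct_change = pct,
             pct_reported = roundPct(pct), t = NA_real_, p = p,
             p_adj = bhAdjust(p), sig = p < 0.05, large = abs(pct) > 50,
             stringsAsFactors = FALSE)
}
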