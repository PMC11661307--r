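test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(dynamic_fraction = 1.2), "dynamic_fraction")
  expect_error(sim_config(n_donors = 0), "n_donors")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sharing_pattern("null", effect_size = 1), "effect_size 0")
  expect_error(sharing_pattern("specific", effect_size = 0), "nonzero")
})

test_that("generators are deterministic under a fixed config", {
  cfg <- sim_config(n_donors = 40, n_genes = 8, n_variants_per_gene = 5,
                    n_cell_types = 2, trans_chains = 0,
                    n_gwas_shared = 0, n_gwas_distinct = 0, seed = 42)
  t1 <- make_ground_truth(cfg); t2 <- make_ground_truth(cfg)
  expect_identical(t1, t2)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  n1 <- simulate_nuclei(cfg, g1, t1); n2 <- simulate_nuclei(cfg, g2, t2)
  expect_identical(n1$counts, n2$counts)
  expect_identical(n1$meta, n2$meta)
})

test_that("dosages follow Hardy-Weinberg at the target frequency", {
  cfg <- sim_config(n_donors = 800, n_genes = 2, n_variants_per_gene = 6,
                    n_cell_types = 1, maf_range = c(0.5, 0.5),
                    ancestry_maf_shift = 0, ld_rho = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  freqs <- apply(g$dosage, 2, function(d) tabulate(d + 1L, 3) / length(d))
  # HWE at p = 0.5: (0.25, 0.5, 0.25), each within 3 binomial SEs
  for (k in 1:3) {
    p0 <- c(0.25, 0.5, 0.25)[k]
    tol <- 3 * sqrt(p0 * (1 - p0) / 800)
    expect_true(all(abs(freqs[k, ] - p0) < tol))
  }
})

test_that("empirical MAF tracks the per-variant target frequency", {
  fx <- fx_sim()
  g <- fx$geno
  emp <- colMeans(g$dosage) / 2
  tol <- 3 * sqrt(g$variants$maf * (1 - g$variants$maf) / (2 * nrow(g$dosage)))
  expect_gt(mean(abs(emp - g$variants$maf) < tol), 0.98)
})

test_that("donor variance of pseudobulk expression increases with donor_re_sd", {
  vars <- vapply(c(0, 0.3, 0.6), function(s) {
    cfg <- sim_config(n_donors = 60, n_genes = 15, n_variants_per_gene = 3,
                      n_cell_types = 1, donor_re_sd = s, pool_effect_sd = 0,
                      dynamic_fraction = 0, trans_chains = 0,
                      n_gwas_shared = 0, n_gwas_distinct = 0,
                      effect_patterns = list(sharing_pattern("null")), seed = 8)
    tr <- make_ground_truth(cfg)
    nu <- simulate_nuclei(cfg, simulate_genotypes(cfg), tr)
    pb <- pb_aggregate(nu)
    cpm <- sweep(pb$raw$CT1 + 0.5, 2, pb$covariates$CT1$depth, "/")
    mean(apply(log(cpm), 1, var))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("counts follow the negative-binomial mean-variance relation", {
  # two donors, constant per-donor mean: var = mu + mu^2/theta
  cfg <- sim_config(n_donors = 2, n_genes = 12, n_variants_per_gene = 2,
                    n_cell_types = 1, nuclei_mean = 1500, nuclei_size = 1e6,
                    nb_dispersion = 4, donor_re_sd = 0, pool_effect_sd = 0,
                    libsize_sdlog = 0, pseudotime_jitter = 0,
                    dynamic_fraction = 0, trans_chains = 0,
                    n_gwas_shared = 0, n_gwas_distinct = 0,
                    effect_patterns = list(sharing_pattern("null")), seed = 5)
  tr <- make_ground_truth(cfg)
  nu <- simulate_nuclei(cfg, simulate_genotypes(cfg), tr)
  d1 <- nu$meta$donor == nu$meta$donor[1]
  y <- as.matrix(nu$counts[, d1])
  mu <- rowMeans(y)
  v_obs <- apply(y, 1, var)
  v_exp <- mu + mu^2 / 4
  keep <- mu > 1
  expect_true(all(abs(v_obs[keep] / v_exp[keep] - 1) < 0.25))
})

test_that("a planted per-allele effect yields the expected pseudobulk fold change", {
  # effect 1 per allele in the active cell type: dosage-2 vs dosage-0 donors
  # differ by a factor of e^2 there and show no fold change elsewhere
  cfg <- sim_config(n_donors = 200, n_genes = 6, n_variants_per_gene = 3,
                    n_cell_types = 2, nuclei_mean = 50, nuclei_size = 1e6,
                    maf_range = c(0.4, 0.5), donor_re_sd = 0.1,
                    pool_effect_sd = 0, dynamic_fraction = 0, trans_chains = 0,
                    n_gwas_shared = 0, n_gwas_distinct = 0,
                    effect_patterns = list(
                      sharing_pattern("specific", active = 1, effect_size = 1)),
                    seed = 1)
  tr <- make_ground_truth(cfg)
  ge <- simulate_genotypes(cfg)
  nu <- simulate_nuclei(cfg, ge, tr)
  pb <- pb_aggregate(nu)
  g <- 1
  vid <- sprintf("%s_v%02d", tr$genes$gene[g], tr$genes$causal_variant[g])
  for (ct in c("CT1", "CT2")) {
    cpm <- pb$raw[[ct]][tr$genes$gene[g], ] / pb$covariates[[ct]]$depth
    dos <- ge$dosage[colnames(pb$raw[[ct]]), vid]
    ratio <- mean(cpm[dos == 2]) / mean(cpm[dos == 0])
    if (ct == "CT1") expect_true(ratio > exp(2) * 0.7 && ratio < exp(2) * 1.4)
    else expect_true(ratio > 0.75 && ratio < 1.35)
  }
})

test_that("ground truth honours the pattern, dynamic and chain settings", {
  cfg0 <- sim_config(n_donors = 30, n_genes = 20, n_cell_types = 3,
                     dynamic_fraction = 0, trans_chains = 3, seed = 2)
  tr0 <- make_ground_truth(cfg0)
  expect_true(all(tr0$genes$dynamic_beta == 0))
  expect_identical(nrow(tr0$chains), 3L)
  # chain targets sit on the other chromosome, beyond any 5 Mb window
  for (i in seq_len(3)) {
    ci <- tr0$genes[tr0$genes$gene == tr0$chains$cis_gene[i], ]
    ti <- tr0$genes[tr0$genes$gene == tr0$chains$trans_gene[i], ]
    expect_true(ci$chrom != ti$chrom)
  }

  cfg1 <- sim_config(n_donors = 30, n_genes = 20, n_cell_types = 4,
                     trans_chains = 0, n_gwas_shared = 0, n_gwas_distinct = 0,
                     effect_patterns = list(sharing_pattern("specific"),
                                            sharing_pattern("null")),
                     seed = 2)
  tr1 <- make_ground_truth(cfg1)
  nn <- tr1$genes$label != "null"
  expect_true(all(lengths(tr1$genes$active[nn]) == 1))
  expect_true(all(lengths(tr1$genes$active[!nn]) == 0))
  expect_true(all(tr1$genes$effect_size[!nn] == 0))
})

test_that("Poisson sampling is recovered in the large-dispersion limit", {
  cfg <- sim_config(n_donors = 2, n_genes = 10, n_variants_per_gene = 2,
                    n_cell_types = 1, nuclei_mean = 1200, nuclei_size = 1e6,
                    nb_dispersion = Inf, donor_re_sd = 0, pool_effect_sd = 0,
                    libsize_sdlog = 0, pseudotime_jitter = 0,
                    dynamic_fraction = 0, trans_chains = 0,
                    n_gwas_shared = 0, n_gwas_distinct = 0,
                    effect_patterns = list(sharing_pattern("null")), seed = 6)
  tr <- make_ground_truth(cfg)
  nu <- simulate_nuclei(cfg, simulate_genotypes(cfg), tr)
  d1 <- nu$meta$donor == nu$meta$donor[1]
  y <- as.matrix(nu$counts[, d1])
  mu <- rowMeans(y)
  v <- apply(y, 1, var)
  keep <- mu > 1
  expect_true(all(abs(v[keep] / mu[keep] - 1) < 0.2))
})
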