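test_that("a noiseless linear signal is recovered exactly", {
  set.seed(1)
  dosage <- matrix(rbinom(40 * 3, 2, 0.4), 40, 3)
  ge <- make_geno(dosage, pos = c(1e5, 2e5, 3e5), n_pcs = 0)
  y <- 0.5 * dosage[, 2]
  pb <- make_pb(list(CTA = matrix(y, 1, 40,
                                  dimnames = list("gX", rownames(ge$dosage)))))
  genes <- data.frame(gene = "gX", chrom = "chr1", tss = 2e5)
  tab <- map_cis(pb, ge, genes, n_pcs = 0, min_donors = 10)
  hit <- tab[tab$variant == "v02", ]
  expect_equal(hit$beta, 0.5, tolerance = 1e-10)
  expect_lt(hit$p, 1e-60)
})

test_that("coefficients match the brute-force normal-equations oracle", {
  set.seed(5)
  for (rep in 1:3) {
    nd <- sample(6:10, 1)
    dosage <- matrix(rbinom(nd * 4, 2, 0.5), nd, 4)
    while (any(apply(dosage, 2, var) == 0))
      dosage <- matrix(rbinom(nd * 4, 2, 0.5), nd, 4)
    ge <- make_geno(dosage, pos = c(1e5, 2e5, 3e5, 4e5), n_pcs = 1)
    y <- rnorm(nd)
    pb <- make_pb(list(CTA = matrix(y, 1, nd,
                                    dimnames = list("gX", rownames(ge$dosage)))))
    genes <- data.frame(gene = "gX", chrom = "chr1", tss = 2e5)
    tab <- map_cis(pb, ge, genes, n_pcs = 1, min_donors = 5)
    for (v in seq_len(4)) {
      X <- cbind(1, ge$pcs[, 1], ge$dosage[, v])
      cf <- solve(t(X) %*% X, t(X) %*% y)
      res <- y - X %*% cf
      s2 <- sum(res^2) / (nd - 3)
      se <- sqrt(s2 * solve(t(X) %*% X)[3, 3])
      row <- tab[tab$variant == colnames(ge$dosage)[v], ]
      expect_equal(row$beta, cf[3], tolerance = 1e-10)
      expect_equal(row$se, se, tolerance = 1e-10)
    }
  }
})

test_that("permuted genotypes yield nominal false-positive rates", {
  cfg <- sim_config(n_donors = 150, n_genes = 500, n_variants_per_gene = 4,
                    n_cell_types = 1, ld_rho = 0, dynamic_fraction = 0,
                    trans_chains = 0, n_gwas_shared = 0, n_gwas_distinct = 0,
                    effect_patterns = list(sharing_pattern("null")), seed = 1)
  tr <- make_ground_truth(cfg)
  ge <- simulate_genotypes(cfg)
  nu <- simulate_nuclei(cfg, ge, tr)
  pb <- pb_normalize(pb_aggregate(nu))
  set.seed(11)
  perm <- sample(nrow(ge$dosage))
  ge$dosage <- ge$dosage[perm, , drop = FALSE]
  rownames(ge$dosage) <- rownames(ge$pcs)
  ge$pcs <- ge$pcs[perm, , drop = FALSE]
  rownames(ge$pcs) <- rownames(ge$dosage)
  tab <- map_cis(pb, ge, nu$genes)
  frac <- mean(tab$p < 0.05)
  expect_lt(abs(frac - 0.05), 2 * sqrt(0.05 * 0.95 / nrow(tab)))
})

test_that("eGene calling is calibrated under the null and powered for effects", {
  # all-null cohort: essentially no eGenes at FDR 5%
  cfg0 <- sim_config(n_donors = 150, n_genes = 100, n_variants_per_gene = 8,
                     n_cell_types = 1, dynamic_fraction = 0, trans_chains = 0,
                     n_gwas_shared = 0, n_gwas_distinct = 0,
                     effect_patterns = list(sharing_pattern("null")), seed = 2)
  tr0 <- make_ground_truth(cfg0)
  nu0 <- simulate_nuclei(cfg0, simulate_genotypes(cfg0), tr0)
  pb0 <- pb_normalize(pb_aggregate(nu0))
  eg0 <- egene_calling(map_cis(pb0, simulate_genotypes(cfg0), nu0$genes))
  expect_lte(mean(eg0$egene), 0.05)

  # planted effects: power above 0.9 at 200 donors
  cfg1 <- sim_config(n_donors = 200, n_genes = 60, n_variants_per_gene = 8,
                     n_cell_types = 1, maf_range = c(0.25, 0.35),
                     effect_size = 0.8, dynamic_fraction = 0, trans_chains = 0,
                     n_gwas_shared = 0, n_gwas_distinct = 0,
                     effect_patterns = list(sharing_pattern("shared_all",
                                                            active = "all")),
                     seed = 2)
  tr1 <- make_ground_truth(cfg1)
  ge1 <- simulate_genotypes(cfg1)
  nu1 <- simulate_nuclei(cfg1, ge1, tr1)
  pb1 <- pb_normalize(pb_aggregate(nu1))
  eg1 <- egene_calling(map_cis(pb1, ge1, nu1$genes))
  expect_gt(mean(eg1$egene), 0.9)
  expect_error(egene_calling(fx_sim()$cis[0, ]), "empty")
})

test_that("lead-variant ties break to the smaller position", {
  tab <- data.frame(gene = "g", variant = c("b", "a"), chrom = "chr1",
                    pos = c(200, 100), cell_type = "CT",
                    beta = c(1, 1), se = c(0.1, 0.1), stat = 10,
                    p = c(1e-5, 1e-5), maf = 0.3, n = 50, dist = 0)
  expect_identical(lead_variants(tab)$variant, "a")
})

test_that("single-causal fine-mapping normalizes and forms credible sets", {
  one <- data.frame(gene = "g1", cell_type = "CT", variant = "v1",
                    chrom = "chr1", pos = 1, beta = 0.5, se = 0.1)
  fm1 <- finemap_abf(one)
  expect_equal(fm1$pip, 1)
  expect_true(fm1$cs)

  ten <- data.frame(gene = "g1", cell_type = "CT",
                    variant = paste0("v", 1:10), chrom = "chr1", pos = 1:10,
                    beta = 0.3, se = 0.1)
  fm10 <- finemap_abf(ten)
  expect_equal(fm10$pip, rep(0.1, 10), tolerance = 1e-12)
  expect_identical(sum(fm10$cs), 10L)

  # z = 0 with equal SEs: uniform by symmetry
  null10 <- transform(ten, beta = 0)
  fm0 <- finemap_abf(null10)
  expect_equal(fm0$pip, rep(0.1, 10), tolerance = 1e-12)

  # PIPs sum to one per gene and ABF is invariant to allele flips
  fx <- fx_sim()
  sub <- fx$cis[fx$cis$cell_type == "CT1", ]
  fm <- finemap_abf(sub)
  sums <- tapply(fm$pip, fm$gene, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  flipped <- transform(sub, beta = -beta)
  expect_equal(finemap_abf(flipped)$pip, fm$pip, tolerance = 1e-12)
})

test_that("credible sets tighten as the z profile sharpens", {
  base <- data.frame(gene = "g1", cell_type = "CT",
                     variant = paste0("v", 1:20), chrom = "chr1", pos = 1:20,
                     se = 0.1)
  sizes <- vapply(c(1, 2, 4, 8), function(sharp) {
    base$beta <- 0.1 * exp(-sharp * (1:20 - 10)^2 / 50)
    sum(finemap_abf(base)$cs)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("MaxCPP takes the best credible-set probability per variant", {
  tab <- data.frame(gene = rep(c("g1", "g2"), each = 2), cell_type = "CT",
                    variant = c("v1", "v2", "v1", "v3"),
                    chrom = "chr1", pos = c(1, 2, 1, 3),
                    beta = c(2, 0.1, 0.5, 0.5), se = 0.1)
  mc <- max_cpp(finemap_abf(tab))
  fm <- finemap_abf(tab)
  expect_equal(mc$maxcpp[mc$variant == "v1"],
               max(fm$pip[fm$variant == "v1" & fm$cs]))
})

test_that("pi0 estimation recovers known alternative fractions", {
  set.seed(21)
  expect_lt(1 - storey_pi0(runif(5000)), 0.05)
  expect_gt(1 - storey_pi0(rep(1e-12, 100)), 0.95)
  # 30/70 alternative/null mixture
  p_mix <- c(runif(3500), 2 * pnorm(-abs(rnorm(1500, 5, 1))))
  pi1 <- 1 - storey_pi0(p_mix)
  expect_lt(abs(pi1 - 0.30), 0.03)
})

test_that("replication pi1 matches the discovery structure", {
  fx <- fx_sim()
  # self-replication of strong signals: lead p-values are tiny, pi1 near 1
  strong <- fx$cis[fx$cis$p < 1e-4, ]
  rep_self <- suppressWarnings(pi1_replication(strong, strong))
  expect_gt(rep_self$pi1, 0.9)
  # under-sized matched sets warn about instability
  tiny <- strong[strong$gene %in% unique(strong$gene)[1:2], ]
  expect_warning(pi1_replication(tiny, tiny), "fewer than 50")
})

test_that("bin density counts overlaps around lead variants", {
  leads <- data.frame(chrom = "chr1", pos = 5e6)
  # one element exactly covering the central bin [5e6, 5e6 + 1e4) (0-based)
  ocr <- data.frame(chrom = "chr1", start = 5e6, end = 5e6 + 1e4)
  prof <- ocr_bin_density(leads, ocr)
  expect_identical(nrow(prof), 200L)
  central <- which(prof$offset == 0)
  expect_equal(prof$count[central], 1)
  expect_equal(sum(prof$count), 1)

  # an element straddling two bins is counted in both
  ocr2 <- data.frame(chrom = "chr1", start = 5e6 - 100, end = 5e6 + 100)
  prof2 <- ocr_bin_density(leads, ocr2)
  expect_equal(sum(prof2$count), 2)
  expect_equal(prof2$count[central - 1], 1)
  expect_equal(prof2$count[central], 1)

  expect_error(ocr_bin_density(leads, ocr, window_bp = 2e6, bin_bp = 3e4),
               "multiple")
})

test_that("uniform elements give a flat bin-density profile", {
  set.seed(9)
  leads <- data.frame(chrom = "chr1", pos = round(runif(30, 2e6, 8e6)))
  starts <- round(runif(2000, 0, 1e7))
  ocr <- data.frame(chrom = "chr1", start = starts, end = starts + 500)
  prof <- ocr_bin_density(leads, ocr)
  lam <- mean(prof$count)
  # per-bin totals are Poisson-ish around the mean
  expect_true(all(abs(prof$count - lam) < 6 * sqrt(lam)))
})

test_that("malformed BED input is rejected", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300"), bad)
  expect_error(ocr_bin_density(data.frame(chrom = "chr1", pos = 1e6), bad),
               "malformed")
})
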