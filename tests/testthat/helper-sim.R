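# Shared fixtures, built once per test run and cached in the helper
# environment. All generators are seeded through sim_config.

.fixtures <- new.env(parent = emptyenv())

# Moderate cohort exercising every effect pattern (120 donors, 3 cell types).
fx_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(n_donors = 120, n_genes = 40, n_variants_per_gene = 15,
                      n_cell_types = 3, seed = 7)
    truth <- make_ground_truth(cfg)
    geno <- simulate_genotypes(cfg)
    nuclei <- simulate_nuclei(cfg, geno, truth)
    pb <- pb_normalize(pb_aggregate(nuclei))
    cis <- map_cis(pb, geno, nuclei$genes)
    .fixtures$sim <- list(cfg = cfg, truth = truth, geno = geno,
                          nuclei = nuclei, pb = pb, cis = cis)
  }
  .fixtures$sim
}

# Minimal hand-built genotype_matrix for oracle tests.
make_geno <- function(dosage, chrom = "chr1", pos = NULL, n_pcs = 2) {
  nd <- nrow(dosage); nv <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(nv) * 1e4
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("D%03d", seq_len(nd))
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%02d", seq_len(nv))
  poly <- apply(dosage, 2, stats::var) > 0
  pcs <- if (any(poly) && n_pcs > 0) {
    sc <- scale(dosage[, poly, drop = FALSE])
    u <- svd(sc, nu = min(n_pcs, nd - 1), nv = 0)$u * sqrt(nd - 1)
    rownames(u) <- rownames(dosage)
    colnames(u) <- paste0("PC", seq_len(ncol(u)))
    u
  } else matrix(0, nd, 0, dimnames = list(rownames(dosage), NULL))
  structure(list(dosage = dosage,
                 variants = data.frame(variant = colnames(dosage),
                                       gene = NA, chrom = chrom, pos = pos,
                                       ref = "A", alt = "G",
                                       maf = pmin(colMeans(dosage) / 2,
                                                  1 - colMeans(dosage) / 2),
                                       stringsAsFactors = FALSE),
                 donors = data.frame(donor = rownames(dosage), pop = 1L),
                 pcs = pcs),
            class = "genotype_matrix")
}

# Minimal normalized pseudobulk holding given residual matrices.
make_pb <- function(residuals, covariates = NULL) {
  cts <- names(residuals)
  structure(list(level = "class", cell_types = cts,
                 raw = lapply(residuals, function(r) matrix(0, nrow(r), ncol(r),
                                                            dimnames = dimnames(r))),
                 covariates = covariates, n_nuclei = NULL,
                 genes = NULL, residuals = residuals),
            class = "pseudobulk")
}
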