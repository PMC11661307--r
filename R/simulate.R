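#' Simulate donor genotypes on two synthetic chromosomes
#'
#' Draws per-variant dosages in Hardy-Weinberg equilibrium at a minor-allele
#' frequency sampled uniformly from `config$maf_range`. Two subpopulations
#' with shifted allele frequencies emulate ancestry structure (exposing the
#' genotype-PC covariate path), and an optional AR(1) haplotype correlation
#' induces local LD within each gene's variant panel. Variant coordinates are
#' deterministic around each gene's TSS so cis windows are well defined and
#' cross-chromosome pairs always exceed the 5 Mb trans distance.
#'
#' @param config A [sim_config()].
#' @return Object of class `genotype_matrix`: list with `dosage` (donors x
#'   variants matrix, entries 0/1/2), `variants` (variant, gene, chrom, pos,
#'   ref, alt, maf = mixture target frequency), `donors` (donor id and
#'   subpopulation), and `pcs` (top genotype principal components).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  genes <- sim_gene_map(config)
  nd <- config$n_donors
  nv <- config$n_variants_per_gene

  variants <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
    pos <- round(seq(genes$tss[g] - 8e5, genes$tss[g] + 8e5, length.out = nv))
    data.frame(variant = sprintf("%s_v%02d", genes$gene[g], seq_len(nv)),
               gene = genes$gene[g], chrom = genes$chrom[g], pos = pos,
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }))

  pop <- rep(c(1L, 2L), length.out = nd)
  maf1 <- runif(nrow(variants), config$maf_range[1], config$maf_range[2])
  shift <- runif(nrow(variants), -config$ancestry_maf_shift, config$ancestry_maf_shift)
  maf2 <- pmin(pmax(maf1 + shift, 0.01), 0.5)
  w1 <- mean(pop == 1L)
  variants$maf <- w1 * maf1 + (1 - w1) * maf2

  rho <- config$ld_rho
  dosage <- matrix(0L, nd, nrow(variants))
  for (g in seq_len(nrow(genes))) {
    cols <- (g - 1L) * nv + seq_len(nv)
    pm <- rbind(maf1[cols], maf2[cols])  # 2 x nv, row = subpopulation
    for (h in 1:2) {                      # two haplotypes per donor
      z <- matrix(rnorm(nd * nv), nd, nv)
      if (rho > 0 && nv > 1) {
        for (j in 2:nv) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      thr <- t(pm)[, pop, drop = FALSE]   # nv x nd target frequencies
      dosage[, cols] <- dosage[, cols] + (pnorm(z) < t(thr))
    }
  }
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- sprintf("D%04d", seq_len(nd))
  colnames(dosage) <- variants$variant

  poly <- apply(dosage, 2, stats::var) > 0
  npc <- min(5L, nd - 1L)
  sc <- scale(dosage[, poly, drop = FALSE])
  pcs <- svd(sc, nu = npc, nv = 0)$u[, seq_len(npc), drop = FALSE] * sqrt(nd - 1)
  rownames(pcs) <- rownames(dosage)
  colnames(pcs) <- paste0("PC", seq_len(npc))

  structure(list(dosage = dosage, variants = variants,
                 donors = data.frame(donor = rownames(dosage), pop = pop,
                                     stringsAsFactors = FALSE),
                 pcs = pcs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d donors x %d variants on %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' Simulate per-nucleus counts with donor-structured negative-binomial noise
#'
#' For each nucleus the count of gene *j* is drawn from a negative binomial
#' with mean
#' \deqn{s_n \exp(\alpha_j + \delta_{j,c} + \beta_j G + \beta_{t,j} t +
#'   \beta_{gt,j} G t + u_{j,d} + \mathrm{pool}_{j,p} + \mathrm{trans}_{j,d})}
#' and dispersion \eqn{\theta}, where \eqn{s_n} is a log-normal library-size
#' factor with cell-type-specific mean, \eqn{G} the dosage of the gene's
#' causal cis variant, \eqn{t} the nucleus pseudotime, and
#' \eqn{u_{j,d} \sim N(0, \sigma_u^2)} a per-gene donor random intercept.
#' Pseudotime is anchored on donor age (scaled to \eqn{[0,1]}) with
#' nucleus-level jitter. Cis effects and the genotype-by-pseudotime
#' interaction act only in the cell types active under the gene's sharing
#' pattern; mediation chains add
#' \eqn{b (a G_{d} + u_{\mathrm{cis},d})} to the trans gene's log mean.
#' `nb_dispersion = Inf` reduces sampling to Poisson.
#'
#' @param config A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#' @param truth Output of [make_ground_truth()].
#' @return Object of class `nucleus_table`: list with `counts` (genes x
#'   nuclei sparse matrix), `meta` (per-nucleus donor, cell type, pseudotime,
#'   mitochondrial fraction, pool, age, sex), and `genes` (coordinates).
#' @export
simulate_nuclei <- function(config, genotypes, truth) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"),
            inherits(truth, "ground_truth"))
  if (nrow(truth$genes) != config$n_genes ||
      nrow(genotypes$dosage) != config$n_donors)
    stop("dimension mismatch between config, genotypes and ground truth", call. = FALSE)
  set.seed(stage_seed(config$seed, "nuclei"))

  nd <- config$n_donors
  ng <- config$n_genes
  cts <- truth$cell_types
  nct <- length(cts)
  donors <- rownames(genotypes$dosage)

  age <- runif(nd, 0, 97)
  sex <- sample(c("F", "M"), nd, replace = TRUE)
  pool <- paste0("P", ceiling(seq_len(nd) / 25))

  # nuclei captured per donor per cell type (may be zero)
  ncap <- matrix(rnbinom(nd * nct, mu = config$nuclei_mean, size = config$nuclei_size),
                 nd, nct)
  N <- sum(ncap)
  d_idx <- rep(rep(seq_len(nd), nct), as.vector(ncap))
  c_idx <- rep(rep(seq_len(nct), each = nd), as.vector(ncap))

  pt <- pmin(pmax(age[d_idx] / 100 + rnorm(N, 0, config$pseudotime_jitter), 0), 1)
  mito <- rbeta(N, 2, 38)
  ct_meanlog <- rnorm(nct, 0, 0.2)
  s <- exp(rnorm(N, ct_meanlog[c_idx], config$libsize_sdlog))

  # per-gene model parameters
  alpha <- rnorm(ng, log(config$base_mean), 0.8)
  delta <- matrix(rnorm(ng * nct, 0, 0.3), ng, nct)
  beta_t <- rnorm(ng, 0, 0.3)
  npool <- length(unique(pool))
  pool_eff <- matrix(rnorm(ng * npool, 0, config$pool_effect_sd), ng, npool)
  u <- matrix(rnorm(ng * nd, 0, config$donor_re_sd), ng, nd)

  # gene x donor dosage of each gene's causal variant
  causal_id <- sprintf("%s_v%02d", truth$genes$gene, truth$genes$causal_variant)
  dos <- t(genotypes$dosage[, causal_id, drop = FALSE])  # ng x nd
  b_eff <- matrix(0, ng, nct, dimnames = list(truth$genes$gene, cts))
  for (g in seq_len(ng)) {
    act <- truth$genes$active[[g]]
    if (length(act)) b_eff[g, act] <- truth$genes$effect_size[g]
  }

  # trans chains: donor-level latent cis signal feeds the trans gene
  trans_term <- matrix(0, ng, nd)
  if (nrow(truth$chains)) {
    for (i in seq_len(nrow(truth$chains))) {
      cg <- match(truth$chains$cis_gene[i], truth$genes$gene)
      tg <- match(truth$chains$trans_gene[i], truth$genes$gene)
      x_cd <- truth$chains$a_path[i] * dos[cg, ] + u[cg, ]
      trans_term[tg, ] <- trans_term[tg, ] + truth$chains$b_path[i] * x_cd
    }
  }

  pool_idx <- match(pool, unique(pool))
  logmu <- alpha +
    delta[, c_idx, drop = FALSE] +
    pool_eff[, pool_idx[d_idx], drop = FALSE] +
    b_eff[, c_idx, drop = FALSE] * dos[, d_idx, drop = FALSE] +
    u[, d_idx, drop = FALSE] +
    trans_term[, d_idx, drop = FALSE] +
    outer(beta_t, pt) +
    (b_eff[, c_idx, drop = FALSE] != 0) * truth$genes$dynamic_beta *
      dos[, d_idx, drop = FALSE] * matrix(pt, ng, N, byrow = TRUE)
  mu <- exp(logmu) * matrix(s, ng, N, byrow = TRUE)
  cnt <- if (is.finite(config$nb_dispersion)) {
    rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
  } else {
    rpois(length(mu), mu)
  }
  counts <- matrix(cnt, ng, N,
                   dimnames = list(truth$genes$gene, sprintf("N%06d", seq_len(N))))

  meta <- data.frame(
    barcode = colnames(counts),
    donor = donors[d_idx],
    cell_type = cts[c_idx],
    pseudotime = pt,
    mito_frac = mito,
    pool = pool[d_idx],
    age = age[d_idx],
    sex = sex[d_idx],
    stringsAsFactors = FALSE
  )
  structure(list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                 meta = meta, genes = truth$genes[, c("gene", "chrom", "tss")]),
            class = "nucleus_table")
}

#' @export
print.nucleus_table <- function(x, ...) {
  cat(sprintf("Nucleus table: %d genes x %d nuclei, %d donors, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$donor)), length(unique(x$meta$cell_type))))
  invisible(x)
}

#' Simulate GWAS summary statistics for the synthetic trait
#'
#' Generates an independent cohort with the same allele frequencies and local
#' LD as the study genotypes, a quantitative trait driven by the causal
#' variants of genes flagged `shared` or `distinct` in the ground truth, and
#' per-variant marginal regression summary statistics. `shared` genes reuse
#' the cis causal variant (colocalized signal); `distinct` genes place the
#' trait signal on another variant in the same window.
#'
#' @param genotypes Output of [simulate_genotypes()] (supplies the variant map).
#' @param truth Output of [make_ground_truth()].
#' @param config A [sim_config()].
#' @param n_gwas GWAS cohort size.
#' @param gamma Per-allele effect of each causal variant on the trait
#'   (phenotype standardized to unit residual variance).
#' @return `data.frame` of class `summary_stats`: variant, chrom, pos, ref,
#'   alt, beta, se, p, n.
#' @export
simulate_gwas <- function(genotypes, truth, config, n_gwas = 5000, gamma = 0.15) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(config$seed, "gwas"))
  v <- genotypes$variants
  nv <- config$n_variants_per_gene
  rho <- config$ld_rho

  # cohort genotypes: HWE at the mixture MAF with the same AR(1) LD
  G <- matrix(0L, n_gwas, nrow(v))
  for (g in seq_len(config$n_genes)) {
    cols <- (g - 1L) * nv + seq_len(nv)
    for (h in 1:2) {
      z <- matrix(rnorm(n_gwas * nv), n_gwas, nv)
      if (rho > 0 && nv > 1)
        for (j in 2:nv) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      G[, cols] <- G[, cols] + (pnorm(z) < matrix(v$maf[cols], n_gwas, nv, byrow = TRUE))
    }
  }

  causal <- which(truth$genes$gwas_status != "none")
  y <- rnorm(n_gwas)
  for (g in causal) {
    cid <- (g - 1L) * nv + truth$genes$gwas_variant[g]
    y <- y + gamma * (G[, cid] - mean(G[, cid]))
  }

  Gc <- scale(G, scale = FALSE)
  vg <- colSums(Gc^2)
  ok <- vg > 0
  beta <- se <- p <- rep(NA_real_, nrow(v))
  beta[ok] <- as.vector(crossprod(Gc[, ok, drop = FALSE], y - mean(y))) / vg[ok]
  sy2 <- sum((y - mean(y))^2)
  rss <- sy2 - beta[ok]^2 * vg[ok]
  se[ok] <- sqrt(rss / (n_gwas - 2) / vg[ok])
  p[ok] <- 2 * pt(-abs(beta[ok] / se[ok]), df = n_gwas - 2)

  out <- data.frame(variant = v$variant, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, beta = beta, se = se, p = p,
                    n = n_gwas, stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  class(out) <- c("summary_stats", "data.frame")
  out
}
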