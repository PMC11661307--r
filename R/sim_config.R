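#' Simulation configuration for the synthetic single-nucleus cohort
#'
#' Builds and validates the parameter set used by [simulate_genotypes()],
#' [make_ground_truth()], [simulate_nuclei()] and [simulate_gwas()]. The
#' defaults describe a desk-scale cohort of 200 donors and 5 cell types with
#' donor-structured negative-binomial counts, a mix of shared, specific and
#' null cis effects, pseudotime-varying effects, and cis-to-trans mediation
#' chains, so that every downstream analysis stage is exercised.
#'
#' @param n_donors Number of donors.
#' @param n_genes Number of genes.
#' @param n_variants_per_gene Number of cis variants simulated per gene.
#' @param n_cell_types Number of cell types (labelled `CT1`, `CT2`, ...).
#' @param maf_range Length-2 numeric in (0, 0.5]: minor-allele frequencies are
#'   drawn uniformly from this interval.
#' @param nuclei_mean,nuclei_size Negative-binomial parameters for the number
#'   of nuclei captured per donor per cell type (mean and size). Donors may
#'   draw zero nuclei for a cell type, in which case they are absent from
#'   that cell type's pseudobulk.
#' @param nb_dispersion Negative-binomial size parameter \eqn{\theta} of the
#'   per-nucleus counts; larger values approach Poisson sampling.
#' @param donor_re_sd Standard deviation of the per-gene donor random
#'   intercept on the log-mean scale.
#' @param effect_patterns List of sharing patterns created with
#'   [sharing_pattern()]. Genes are assigned patterns by cycling through this
#'   list in proportion to the `frac` attribute of each pattern.
#' @param effect_size Per-allele effect on the log mean used for non-null
#'   patterns that do not specify their own size.
#' @param dynamic_fraction Fraction of non-null genes given a genotype by
#'   pseudotime interaction effect.
#' @param dynamic_beta Interaction coefficient (log-mean per allele per unit
#'   pseudotime) for dynamic genes.
#' @param trans_chains Number of cis-to-trans mediation triplets
#'   (variant, cis gene, trans gene) planted on different chromosomes.
#' @param trans_a,trans_b Path coefficients of the mediation chains: `trans_a`
#'   is the per-allele effect on the cis gene, `trans_b` the effect of the
#'   cis-gene donor-level signal on the trans gene's log mean.
#' @param n_gwas_shared,n_gwas_distinct Number of genes whose cis causal
#'   variant is shared with a simulated GWAS trait, and number whose GWAS
#'   signal sits on a different variant in the same window.
#' @param ld_rho AR(1) haplotype correlation between adjacent variants of a
#'   gene (0 = independent variants).
#' @param ancestry_maf_shift Half-width of the uniform shift applied to the
#'   MAF of the second subpopulation, emulating two-population structure.
#' @param pool_effect_sd SD of the gene-specific sample-pool batch effect on
#'   the log mean.
#' @param libsize_sdlog SD (log scale) of the per-nucleus library-size factor.
#' @param pseudotime_jitter SD of the nucleus-level jitter added to the
#'   donor-age-anchored pseudotime (on the \eqn{[0, 1]} scale).
#' @param base_mean Baseline expected counts per gene per nucleus.
#' @param seed Integer seed; all generators derive their randomness from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sharing_pattern()], [simulate_genotypes()], [simulate_nuclei()]
#' @export
sim_config <- function(n_donors = 200,
                       n_genes = 100,
                       n_variants_per_gene = 25,
                       n_cell_types = 5,
                       maf_range = c(0.1, 0.5),
                       nuclei_mean = 10,
                       nuclei_size = 6,
                       nb_dispersion = 8,
                       donor_re_sd = 0.3,
                       effect_patterns = default_patterns(n_cell_types),
                       effect_size = 0.5,
                       dynamic_fraction = 0.15,
                       dynamic_beta = 0.8,
                       trans_chains = 4,
                       trans_a = 0.6,
                       trans_b = 1.0,
                       n_gwas_shared = 3,
                       n_gwas_distinct = 2,
                       ld_rho = 0.25,
                       ancestry_maf_shift = 0.1,
                       pool_effect_sd = 0.2,
                       libsize_sdlog = 0.4,
                       pseudotime_jitter = 0.15,
                       base_mean = 8,
                       seed = 1L) {
  cfg <- list(
    n_donors = as.integer(n_donors), n_genes = as.integer(n_genes),
    n_variants_per_gene = as.integer(n_variants_per_gene),
    n_cell_types = as.integer(n_cell_types),
    maf_range = as.numeric(maf_range),
    nuclei_mean = nuclei_mean, nuclei_size = nuclei_size,
    nb_dispersion = nb_dispersion, donor_re_sd = donor_re_sd,
    effect_patterns = effect_patterns, effect_size = effect_size,
    dynamic_fraction = dynamic_fraction, dynamic_beta = dynamic_beta,
    trans_chains = as.integer(trans_chains),
    trans_a = trans_a, trans_b = trans_b,
    n_gwas_shared = as.integer(n_gwas_shared),
    n_gwas_distinct = as.integer(n_gwas_distinct),
    ld_rho = ld_rho, ancestry_maf_shift = ancestry_maf_shift,
    pool_effect_sd = pool_effect_sd, libsize_sdlog = libsize_sdlog,
    pseudotime_jitter = pseudotime_jitter, base_mean = base_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_donors", "n_genes", "n_variants_per_gene", "n_cell_types")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("'", f, "' must be a count >= 1", call. = FALSE)
  }
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] > mr[2])
    stop("'maf_range' must be an ordered pair", call. = FALSE)
  if (mr[1] <= 0 || mr[2] > 0.5)
    stop("'maf_range' bounds must lie in (0, 0.5]", call. = FALSE)
  if (cfg$dynamic_fraction < 0 || cfg$dynamic_fraction > 1)
    stop("'dynamic_fraction' must lie in [0, 1]", call. = FALSE)
  if (cfg$donor_re_sd < 0) stop("'donor_re_sd' must be >= 0", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("'nb_dispersion' must be > 0", call. = FALSE)
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("'ld_rho' must lie in [0, 1)", call. = FALSE)
  if (cfg$trans_chains < 0) stop("'trans_chains' must be >= 0", call. = FALSE)
  for (p in cfg$effect_patterns) {
    if (!inherits(p, "sharing_pattern")) stop("effect_patterns entries must be sharing_pattern objects", call. = FALSE)
  }
  invisible(cfg)
}

#' Declare a cis-effect sharing pattern across cell types
#'
#' A sharing pattern states in which cell types a gene's cis effect is active.
#' `label = "null"` requires a zero effect and an empty active set; all other
#' labels require a nonempty active set and (if supplied) a nonzero effect.
#'
#' @param label One of `"specific"`, `"shared_all"`, `"shared_subset"`,
#'   `"null"`.
#' @param active Integer indices (or `"all"`) of the active cell types.
#'   Ignored for `"null"`. For `"specific"` the active type is rotated across
#'   genes when `active = NA`.
#' @param effect_size Optional per-allele effect on the log mean; `NA` defers
#'   to the `effect_size` of the [sim_config()].
#' @param frac Relative share of genes assigned this pattern.
#' @return An object of class `sharing_pattern`.
#' @export
sharing_pattern <- function(label, active = NA, effect_size = NA, frac = 1) {
  label <- match.arg(label, c("specific", "shared_all", "shared_subset", "null"))
  if (label == "null") {
    if (!all(is.na(active)) && length(active)) stop("null pattern must have an empty active set", call. = FALSE)
    if (!is.na(effect_size) && effect_size != 0) stop("null pattern must have effect_size 0", call. = FALSE)
    active <- integer(0)
    effect_size <- 0
  } else {
    if (!is.na(effect_size) && effect_size == 0)
      stop("non-null pattern must have a nonzero effect size", call. = FALSE)
  }
  structure(list(label = label, active = active, effect_size = effect_size, frac = frac),
            class = "sharing_pattern")
}

#' Default pattern mix: specific, shared-all, shared-subset and null genes
#' @param n_cell_types Number of cell types in the simulation.
#' @return List of [sharing_pattern()] objects.
#' @export
default_patterns <- function(n_cell_types) {
  pats <- list(
    sharing_pattern("specific", active = NA, frac = 0.30),
    sharing_pattern("shared_all", active = "all", frac = 0.20),
    sharing_pattern("null", frac = 0.40)
  )
  if (n_cell_types >= 3) {
    pats <- append(pats, list(
      sharing_pattern("shared_subset", active = seq_len(ceiling(n_cell_types / 2)), frac = 0.10)
    ), after = 2)
  }
  pats
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic single-nucleus cohort configuration\n")
  cat(sprintf("  %d donors, %d genes x %d cis variants, %d cell types\n",
              x$n_donors, x$n_genes, x$n_variants_per_gene, x$n_cell_types))
  cat(sprintf("  MAF U(%.2f, %.2f), LD rho %.2f, NB theta %.1f, donor RE sd %.2f\n",
              x$maf_range[1], x$maf_range[2], x$ld_rho, x$nb_dispersion, x$donor_re_sd))
  cat(sprintf("  dynamic fraction %.2f (beta %.2f), %d trans chains, seed %d\n",
              x$dynamic_fraction, x$dynamic_beta, x$trans_chains, x$seed))
  invisible(x)
}

# Deterministic stage seed below 2^31, derived from the config seed and a
# stage label so stages are independent but reproducible.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Gene coordinates on the two synthetic chromosomes
#'
#' Genes are laid out deterministically: split across chromosomes `chr1` and
#' `chr2` with transcription start sites every 3 Mb, so cis windows (1 Mb) of
#' neighbouring genes never overlap and cross-chromosome pairs always satisfy
#' the 5 Mb trans-distance rule.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with columns `gene`, `chrom`, `tss`.
#' @export
sim_gene_map <- function(config) {
  ng <- config$n_genes
  n1 <- ceiling(ng / 2)
  chrom <- rep(c("chr1", "chr2"), c(n1, ng - n1))
  idx <- c(seq_len(n1), seq_len(ng - n1))
  data.frame(
    gene = sprintf("G%03d", seq_len(ng)),
    chrom = chrom,
    tss = 3e6 * idx,
    stringsAsFactors = FALSE
  )
}
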