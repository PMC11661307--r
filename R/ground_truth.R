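#' Assign ground-truth effect configurations to genes
#'
#' Gives every gene a sharing pattern (which cell types its cis effect is
#' active in), designates dynamic genes (genotype x pseudotime interaction),
#' plants cis-to-trans mediation chains across the two synthetic chromosomes,
#' and flags genes whose causal variant is shared with (or distinct from) the
#' simulated GWAS trait. All assignments are reproducible under the config
#' seed and serve as the oracle for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: a list with
#'   \describe{
#'     \item{genes}{per-gene table: coordinates, pattern label, active cell
#'       types, effect size, index of the causal cis variant, dynamic
#'       interaction coefficient, GWAS sharing status.}
#'     \item{chains}{mediation triplets (variant, cis gene, trans gene) with
#'       path coefficients `a_path` (variant to cis gene, per allele, log
#'       mean) and `b_path` (cis-gene donor signal to trans-gene log mean).}
#'     \item{cell_types}{cell-type labels.}
#'   }
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "truth"))
  genes <- sim_gene_map(config)
  ng <- config$n_genes
  cts <- sprintf("CT%d", seq_len(config$n_cell_types))

  # expand pattern mix to per-gene assignments, largest-remainder rounding
  fracs <- vapply(config$effect_patterns, `[[`, numeric(1), "frac")
  fracs <- fracs / sum(fracs)
  n_per <- floor(fracs * ng)
  rem <- ng - sum(n_per)
  if (rem > 0) {
    o <- order(fracs * ng - n_per, decreasing = TRUE)
    n_per[o[seq_len(rem)]] <- n_per[o[seq_len(rem)]] + 1L
  }
  pat_idx <- rep(seq_along(config$effect_patterns), n_per)
  pat_idx <- pat_idx[sample.int(ng)]

  specific_rot <- 0L
  label <- character(ng); eff <- numeric(ng); active <- vector("list", ng)
  for (g in seq_len(ng)) {
    p <- config$effect_patterns[[pat_idx[g]]]
    label[g] <- p$label
    eff[g] <- if (is.na(p$effect_size)) config$effect_size else p$effect_size
    if (p$label == "null") {
      eff[g] <- 0
      active[[g]] <- character(0)
    } else if (p$label == "specific") {
      if (all(is.na(p$active))) {
        specific_rot <- specific_rot %% config$n_cell_types + 1L
        active[[g]] <- cts[specific_rot]
      } else active[[g]] <- cts[p$active]
    } else if (identical(p$active, "all")) {
      active[[g]] <- cts
    } else {
      active[[g]] <- cts[p$active]
    }
  }

  # causal cis variant: middle of the local panel, jittered
  causal <- pmin(pmax(round(config$n_variants_per_gene / 2) +
                        sample(-2:2, ng, replace = TRUE), 1L),
                 config$n_variants_per_gene)

  # dynamic genes drawn from the non-null genes
  nonnull <- which(label != "null")
  n_dyn <- round(config$dynamic_fraction * length(nonnull))
  dyn_beta <- numeric(ng)
  if (n_dyn > 0) dyn_beta[sample(nonnull, n_dyn)] <- config$dynamic_beta

  # trans chains: cis gene on chr1, trans gene on chr2; chain sources are
  # grouped in threes so a planted hub (>= 3 targets) exists when chains >= 3
  chains <- data.frame(variant = character(0), cis_gene = character(0),
                       trans_gene = character(0), a_path = numeric(0),
                       b_path = numeric(0), stringsAsFactors = FALSE)
  if (config$trans_chains > 0) {
    chr1_nonnull <- intersect(nonnull, which(genes$chrom == "chr1"))
    chr2_null <- intersect(which(label == "null"), which(genes$chrom == "chr2"))
    n_src <- ceiling(config$trans_chains / 3)
    if (length(chr1_nonnull) < n_src || length(chr2_null) < config$trans_chains)
      stop("trans_chains exceeds available gene pairs for the configured cohort",
           call. = FALSE)
    src <- sample(chr1_nonnull, n_src)
    tgt <- sample(chr2_null, config$trans_chains)
    cis_gene <- src[ceiling(seq_len(config$trans_chains) / 3)]
    chains <- data.frame(
      variant = sprintf("%s_v%02d", genes$gene[cis_gene], causal[cis_gene]),
      cis_gene = genes$gene[cis_gene],
      trans_gene = genes$gene[tgt],
      a_path = config$trans_a,
      b_path = config$trans_b,
      stringsAsFactors = FALSE
    )
    # chain source genes get a guaranteed cis effect of a_path in every cell
    # type so that the mediating cis signal exists at the pseudobulk level
    for (g in unique(cis_gene)) {
      label[g] <- "shared_all"
      active[[g]] <- cts
      eff[g] <- config$trans_a
      dyn_beta[g] <- 0
    }
  }

  # GWAS sharing: shared genes reuse the cis causal variant, distinct genes
  # get a separate GWAS causal variant in the same window
  gwas_status <- rep("none", ng)
  gwas_variant <- rep(NA_integer_, ng)
  eligible <- setdiff(nonnull, match(unique(chains$cis_gene), genes$gene))
  n_sh <- min(config$n_gwas_shared, length(eligible))
  sh <- if (n_sh > 0) sample(eligible, n_sh) else integer(0)
  gwas_status[sh] <- "shared"
  gwas_variant[sh] <- causal[sh]
  left <- setdiff(eligible, sh)
  n_di <- min(config$n_gwas_distinct, length(left))
  di <- if (n_di > 0) sample(left, n_di) else integer(0)
  gwas_status[di] <- "distinct"
  for (g in di) {
    far <- which(abs(seq_len(config$n_variants_per_gene) - causal[g]) >=
                   ceiling(config$n_variants_per_gene / 3))
    gwas_variant[g] <- if (length(far)) sample(far, 1) else causal[g]
  }

  out <- list(
    genes = cbind(genes, data.frame(
      label = label, effect_size = eff, causal_variant = causal,
      dynamic_beta = dyn_beta, gwas_status = gwas_status,
      gwas_variant = gwas_variant, stringsAsFactors = FALSE
    )),
    chains = chains,
    cell_types = cts
  )
  out$genes$active <- active
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(x$genes$label)
  cat("Ground truth:", nrow(x$genes), "genes (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  cat("  dynamic genes:", sum(x$genes$dynamic_beta != 0),
      "| trans chains:", nrow(x$chains),
      "| GWAS shared/distinct:", sum(x$genes$gwas_status == "shared"), "/",
      sum(x$genes$gwas_status == "distinct"), "\n")
  invisible(x)
}
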