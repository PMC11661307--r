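#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: simulation parameters,
#' stage toggles, and every analysis threshold. The configuration can be
#' written to and read from YAML ([write_pipeline_config()],
#' [read_pipeline_config()]).
#'
#' @param out_dir Output directory for stage tables and the manifest.
#' @param seed Global seed; every stochastic stage derives its own seed
#'   deterministically from it and the stage name.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param stages Character vector of stages to run, in dependency order.
#' @param cis_window,n_pcs,min_donors Cis mapping parameters.
#' @param factor_grid Hidden-factor counts tried by the sweep.
#' @param fdr FDR level for eGene, dynamic and trans calls.
#' @param specificity_threshold Composite-test call threshold.
#' @param pp4_thresholds Colocalization reporting thresholds.
#' @param sidak_k Sidak test count for trans correction.
#' @param trans_min_distance Minimum trans distance (bp).
#' @param ld_min Minimum LD r-squared for mediation candidates.
#' @param mappability_min Minimum gene mappability for trans mapping.
#' @param mhc Optional MHC exclusion interval (`"chrom:start-end"`).
#' @param dynamic_max_genes Cap on (gene, cell type) pairs fitted by the
#'   dynamic stage (most significant eGenes first).
#' @param background_n Background variant-gene pairs for prior fitting.
#' @param gwas_n GWAS cohort size for the simulated trait.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir = tempfile("snqtl_run_"),
                                    seed = 1L,
                                    sim = list(),
                                    stages = c("simulate", "pseudobulk", "cis",
                                               "finemap", "specificity", "coloc",
                                               "dynamic", "trans", "mediate",
                                               "enrich"),
                                    cis_window = 1e6, n_pcs = 5, min_donors = 30,
                                    factor_grid = c(0, 5, 10),
                                    fdr = 0.05,
                                    specificity_threshold = 0.5,
                                    pp4_thresholds = c(0.5, 0.8),
                                    sidak_k = 1e5,
                                    trans_min_distance = 5e6,
                                    ld_min = 0.75,
                                    mappability_min = 0.8,
                                    mhc = NULL,
                                    dynamic_max_genes = 12,
                                    background_n = 2000,
                                    gwas_n = 5000) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return The path (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

# Polynomial rolling hash of the deparsed configuration (kept in 31 bits).
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

stage_deps <- list(
  simulate = character(0),
  pseudobulk = "simulate",
  cis = "pseudobulk",
  finemap = "cis",
  specificity = "cis",
  coloc = "cis",
  dynamic = "cis",
  trans = c("cis", "coloc"),
  mediate = "trans",
  enrich = c("dynamic", "coloc")
)

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order: simulate (genotypes,
#' ground truth, nuclei, GWAS trait), pseudobulk aggregation and
#' normalization with hidden-factor selection, cis-eQTL mapping and eGene
#' calling, fine-mapping, multivariate shrinkage with the composite
#' specificity scan, colocalization, dynamic eQTL detection, trans mapping
#' with Sidak/BH correction and hub detection, cis-mediation, and the
#' dynamic-coloc enrichment. Each stage writes a TSV (prefixed with a
#' comment line naming the stage and the configuration hash) under
#' `config$out_dir`, and the manifest records seeds, row counts and the
#' configuration hash. A stage whose dependency is disabled fails fast
#' naming the missing stage.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]) or a
#'   path to a YAML configuration.
#' @return Object of class `pipeline_manifest` (also written as
#'   `manifest.json`); the in-memory stage results are attached as
#'   `attr(, "state")`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stages <- intersect(names(stage_deps), config$stages)
  for (st in stages) {
    miss <- setdiff(stage_deps[[st]], stages)
    if (length(miss))
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  S <- new.env(parent = emptyenv())
  manifest <- list(package = "snqtl",
                   version = as.character(utils::packageVersion("snqtl")),
                   config_hash = hash, seed = config$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  emit <- function(df, name, stage) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# stage: %s  config: %s", stage, hash), con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
  }
  record <- function(stage, rows, extra = list()) {
    manifest$stages[[stage]] <<- c(list(seed = stage_seed(config$seed, stage),
                                        rows = rows), extra)
  }

  if ("simulate" %in% stages) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    S$config <- do.call(sim_config, sim_args)
    S$truth <- make_ground_truth(S$config)
    S$geno <- simulate_genotypes(S$config)
    S$nuclei <- simulate_nuclei(S$config, S$geno, S$truth)
    S$gwas <- simulate_gwas(S$geno, S$truth, S$config, n_gwas = config$gwas_n)
    emit(S$gwas, "gwas_summary", "simulate")
    record("simulate", ncol(S$nuclei$counts),
           list(donors = S$config$n_donors, genes = S$config$n_genes))
  }
  if ("pseudobulk" %in% stages) {
    S$pb <- pb_normalize(pb_aggregate(S$nuclei))
    sweep_res <- hidden_factor_sweep(S$pb, S$geno, S$nuclei$genes,
                                     grid = config$factor_grid,
                                     window_bp = config$cis_window,
                                     n_pcs = config$n_pcs,
                                     min_donors = config$min_donors)
    S$n_factors <- sweep_res$selected
    S$factors <- if (S$n_factors > 0) {
      lapply(S$pb$residuals, function(r) {
        s <- svd(scale(t(r), scale = FALSE), nu = S$n_factors, nv = 0)
        u <- s$u * rep(s$d[seq_len(ncol(s$u))], each = nrow(s$u))
        rownames(u) <- colnames(r)
        u
      })
    } else NULL
    emit(sweep_res$sweep, "factor_sweep", "pseudobulk")
    record("pseudobulk", sum(vapply(S$pb$residuals, nrow, integer(1))),
           list(selected_factors = S$n_factors))
  }
  if ("cis" %in% stages) {
    S$cis <- map_cis(S$pb, S$geno, S$nuclei$genes, window_bp = config$cis_window,
                     n_pcs = config$n_pcs, factors = S$factors,
                     min_donors = config$min_donors)
    S$egenes <- egene_calling(S$cis, fdr = config$fdr)
    emit(S$cis, "cis_eqtl", "cis")
    emit(S$egenes, "egenes", "cis")
    record("cis", nrow(S$cis), list(egenes = sum(S$egenes$egene)))
  }
  if ("finemap" %in% stages) {
    eg <- S$egenes[S$egenes$egene, ]
    sub <- S$cis[paste(S$cis$gene, S$cis$cell_type) %in%
                   paste(eg$gene, eg$cell_type), , drop = FALSE]
    S$finemap <- finemap_abf(sub)
    S$maxcpp <- max_cpp(S$finemap)
    emit(S$finemap, "finemap", "finemap")
    emit(S$maxcpp, "maxcpp", "finemap")
    record("finemap", nrow(S$finemap), list(credible = sum(S$finemap$cs)))
  }
  if ("specificity" %in% stages) {
    lead_panel <- effect_panel(S$cis, genes = unique(S$egenes$gene[S$egenes$egene]))
    bg <- background_panel(S$cis, n = config$background_n,
                           seed = stage_seed(config$seed, "background"))
    S$prior <- fit_prior(rbind_panels(lead_panel, bg))
    S$posterior <- posterior_panel(lead_panel, S$prior)
    S$spec <- specificity_scan(S$posterior,
                               threshold = config$specificity_threshold)
    emit(S$spec, "specificity", "specificity")
    record("specificity", nrow(S$spec),
           list(specific = sum(S$spec$specific)))
  }
  if ("coloc" %in% stages) {
    S$coloc <- coloc_scan(S$cis, S$gwas)
    emit(S$coloc, "coloc", "coloc")
    record("coloc", nrow(S$coloc),
           list(pp4_ge_0.5 = sum(S$coloc$PP4 >= 0.5),
                pp4_ge_0.8 = sum(S$coloc$PP4 >= 0.8)))
  }
  if ("dynamic" %in% stages) {
    eg <- S$egenes[S$egenes$egene, ]
    eg <- eg[order(eg$q, eg$p_bonf, eg$gene), ]
    eg <- utils::head(eg, config$dynamic_max_genes)
    S$dynamic <- dynamic_scan(S$nuclei, eg, S$geno, fdr = config$fdr)
    emit(S$dynamic, "dynamic", "dynamic")
    record("dynamic", nrow(S$dynamic),
           list(dynamic_egenes = sum(S$dynamic$dynamic)))
  }
  if ("trans" %in% stages) {
    cand <- unique(c(S$egenes$variant[S$egenes$egene],
                     S$gwas$variant[S$gwas$p < 5e-8]))
    S$trans <- map_trans(S$pb, S$geno, S$nuclei$genes, cand,
                         min_distance = config$trans_min_distance,
                         mhc = config$mhc, n_pcs = config$n_pcs,
                         min_donors = config$min_donors)
    S$trans_sig <- trans_significance(S$trans, k = config$sidak_k,
                                      fdr = config$fdr)
    S$hubs <- find_hubs(S$trans_sig[S$trans_sig$significant, ])
    emit(S$trans_sig, "trans", "trans")
    emit(S$hubs, "trans_hubs", "trans")
    record("trans", nrow(S$trans),
           list(significant = sum(S$trans_sig$significant),
                hubs = nrow(S$hubs)))
  }
  if ("mediate" %in% stages) {
    S$mediation <- mediate(S$trans_sig[S$trans_sig$significant, ],
                           S$egenes[S$egenes$egene, ], S$geno, S$pb,
                           ld_min = config$ld_min, fdr = config$fdr)
    emit(as.data.frame(S$mediation), "mediation", "mediate")
    record("mediate", nrow(S$mediation),
           list(pi1 = attr(S$mediation, "pi1")))
  }
  if ("enrich" %in% stages) {
    universe <- unique(S$dynamic$gene)
    dyn <- unique(S$dynamic$gene[S$dynamic$dynamic])
    col <- intersect(unique(S$coloc$gene[S$coloc$PP4 >= 0.5]), universe)
    S$enrich <- coloc_enrichment(dyn, col, universe,
                                 seed = stage_seed(config$seed, "enrich"))
    record("enrich", 1L,
           list(observed = S$enrich$observed, fold = S$enrich$fold))
  }

  class(manifest) <- "pipeline_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(manifest, "state") <- S
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("snqtl pipeline run (config %s, seed %d)\n", x$config_hash, x$seed))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    extra <- setdiff(names(st), c("seed", "rows"))
    cat(sprintf("  %-12s rows %-7s %s\n", nm, st$rows,
                paste(vapply(extra, function(e) paste0(e, "=",
                      format(st[[e]], digits = 4)), ""), collapse = " ")))
  }
  invisible(x)
}
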