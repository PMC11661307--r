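#' Fit a negative-binomial mixed model for a dynamic (pseudotime) eQTL
#'
#' Models per-nucleus counts of one gene in one cell type as negative
#' binomial with log mean linear in pseudotime, allele dosage and their
#' interaction, with age, sex and mitochondrial rate as fixed covariates, a
#' per-donor random intercept for the repeated nuclei of each donor, and the
#' nucleus library size as a log offset (the default; set
#' `libsize_as_covariate = TRUE` to estimate a free coefficient instead).
#' The interaction Wald p-value tests whether the genetic effect changes
#' along the trajectory. Fitting uses Laplace-approximate maximum likelihood
#' via \pkg{glmmTMB}.
#'
#' @param nuclei A `nucleus_table`.
#' @param gene Gene identifier (row of the count matrix).
#' @param dosage Named numeric vector of allele dosages by donor.
#' @param cell_type Cell type whose nuclei are analysed.
#' @param libsize_as_covariate Estimate log library size as a fixed effect
#'   instead of an offset.
#' @param min_donors Minimum donors with nuclei in the cell type.
#' @param min_nuclei Minimum nuclei per retained donor.
#' @return Object of class `dynamic_fit`: coefficient table (estimate, SE,
#'   z, p), interaction statistics, NB dispersion `theta`, donor
#'   random-intercept SD (0 with `boundary = TRUE` when the variance
#'   collapses to the boundary and the fit reduces to a NB GLM),
#'   convergence flag and sample sizes.
#' @export
fit_nb_glmm <- function(nuclei, gene, dosage, cell_type,
                        libsize_as_covariate = FALSE,
                        min_donors = 20, min_nuclei = 1) {
  stopifnot(inherits(nuclei, "nucleus_table"))
  meta <- nuclei$meta
  sel <- which(meta$cell_type == cell_type)
  if (!length(sel)) stop("no nuclei of cell type ", cell_type, call. = FALSE)
  keep_donor <- names(which(table(meta$donor[sel]) >= min_nuclei))
  sel <- sel[meta$donor[sel] %in% keep_donor]
  d <- data.frame(
    y = as.vector(nuclei$counts[gene, sel]),
    pstime = meta$pseudotime[sel],
    donor = factor(meta$donor[sel]),
    age = meta$age[sel] / 100,
    sex = meta$sex[sel],
    mito = meta$mito_frac[sel],
    log_ls = log(pmax(Matrix::colSums(nuclei$counts[, sel, drop = FALSE]), 1)),
    stringsAsFactors = FALSE
  )
  d$dosage <- dosage[as.character(d$donor)]
  if (anyNA(d$dosage)) stop("dosage missing for some donors", call. = FALSE)
  if (stats::var(d$dosage) == 0) stop("dosage does not vary", call. = FALSE)
  if (nlevels(d$donor) < min_donors)
    stop("fewer than ", min_donors, " donors with nuclei in ", cell_type, call. = FALSE)

  terms <- c("pstime * dosage", "age", "mito")
  if (length(unique(d$sex)) > 1) terms <- c(terms, "sex")
  terms <- c(terms,
             if (libsize_as_covariate) "log_ls" else "offset(log_ls)")
  form <- stats::reformulate(c(terms, "(1 | donor)"), response = "y")
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(form, family = glmmTMB::nbinom2, data = d)
  )
  donor_sd <- sqrt(as.numeric(glmmTMB::VarCorr(fit)$cond$donor))
  boundary <- FALSE
  # Boundary handling for the variance components. Near sigma = 0 the
  # profile likelihood is essentially flat, so the optimizer can stop at a
  # small spurious variance; following the singular-fit convention, a
  # component is set to its boundary value when the likelihood ratio against
  # the boundary is below the 5% critical value of the boundary-corrected
  # null (0.5 chi2_0 + 0.5 chi2_1), i.e. 2*dLL < 2.71. The same rule
  # collapses a vanishing overdispersion (theta very large) to the Poisson
  # limit. Components clearly supported by the data are never touched.
  lr_crit <- stats::qchisq(0.90, df = 1)
  if (!is.na(donor_sd) && donor_sd < 0.1) {
    red <- suppressWarnings(
      glmmTMB::glmmTMB(stats::reformulate(terms, response = "y"),
                       family = glmmTMB::nbinom2, data = d)
    )
    ll_full <- as.numeric(stats::logLik(fit))
    ll_red <- as.numeric(stats::logLik(red))
    if (is.finite(ll_red) &&
        (!is.finite(ll_full) || 2 * (ll_full - ll_red) < lr_crit)) {
      fit <- red
      donor_sd <- 0
      boundary <- TRUE
    }
  }
  if (boundary && glmmTMB::sigma(fit) > 50) {
    pois <- suppressWarnings(
      glmmTMB::glmmTMB(stats::reformulate(terms, response = "y"),
                       family = stats::poisson(), data = d)
    )
    ll_nb <- as.numeric(stats::logLik(fit))
    ll_pois <- as.numeric(stats::logLik(pois))
    if (is.finite(ll_pois) &&
        (!is.finite(ll_nb) || 2 * (ll_nb - ll_pois) < lr_crit)) {
      fit <- pois
    }
  }
  sm <- summary(fit)
  co <- sm$coefficients$cond
  converged <- isTRUE(fit$fit$convergence == 0) && !anyNA(co[, "Std. Error"])
  int <- co["pstime:dosage", ]
  structure(list(
    coefficients = co,
    beta_interaction = unname(int["Estimate"]),
    se_interaction = unname(int["Std. Error"]),
    z_interaction = unname(int["z value"]),
    p_interaction = unname(int["Pr(>|z|)"]),
    theta = if (fit$modelInfo$family$family == "poisson") Inf
            else glmmTMB::sigma(fit),
    donor_sd = donor_sd,
    boundary = boundary,
    converged = converged,
    n_nuclei = nrow(d), n_donors = nlevels(d$donor),
    loglik = as.numeric(stats::logLik(fit)),
    gene = gene, cell_type = cell_type
  ), class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("Dynamic eQTL fit: %s in %s (%d nuclei, %d donors)%s\n",
              x$gene, x$cell_type, x$n_nuclei, x$n_donors,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat(sprintf("  interaction beta %.4f (SE %.4f), Wald p %.3g\n",
              x$beta_interaction, x$se_interaction, x$p_interaction))
  cat(sprintf("  theta %.2f, donor RE sd %.3f\n", x$theta, x$donor_sd))
  invisible(x)
}

#' Scan lead variants for dynamic eQTL effects
#'
#' Fits the negative-binomial mixed model of [fit_nb_glmm()] for every
#' (gene, cell type) lead pair and applies Benjamini-Hochberg correction to
#' the interaction p-values within each cell type. Non-converged fits are
#' retained and flagged, not dropped.
#'
#' @param nuclei A `nucleus_table`.
#' @param leads `data.frame` with columns `gene`, `variant`, `cell_type`
#'   (e.g. eGene leads from [egene_calling()]).
#' @param genotypes A `genotype_matrix` supplying dosages.
#' @param fdr FDR threshold for dynamic eGene calls.
#' @param ... Passed to [fit_nb_glmm()].
#' @return `data.frame`: gene, cell_type, variant, interaction estimate, SE,
#'   z, p, q, dynamic flag, convergence flag.
#' @export
dynamic_scan <- function(nuclei, leads, genotypes, fdr = 0.05, ...) {
  if (!nrow(leads)) stop("empty lead table", call. = FALSE)
  rows <- vector("list", nrow(leads))
  for (i in seq_len(nrow(leads))) {
    fit <- tryCatch(
      fit_nb_glmm(nuclei, leads$gene[i],
                  genotypes$dosage[, leads$variant[i]],
                  leads$cell_type[i], ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    rows[[i]] <- data.frame(
      gene = leads$gene[i], cell_type = leads$cell_type[i],
      variant = leads$variant[i],
      beta_interaction = fit$beta_interaction, se = fit$se_interaction,
      z = fit$z_interaction, p = fit$p_interaction,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no lead pair could be fitted", call. = FALSE)
  out$q <- NA_real_
  for (ct in unique(out$cell_type)) {
    s <- out$cell_type == ct
    out$q[s] <- p.adjust(out$p[s], method = "BH")
  }
  out$dynamic <- out$q <= fdr
  rownames(out) <- NULL
  out
}

#' Resampling enrichment of dynamic eGenes among colocalized genes
#'
#' Counts the overlap between dynamic eGenes and colocalized genes, then
#' draws `rounds` random gene sets of the same size as the dynamic set
#' (without replacement from the universe) to build the null distribution of
#' the overlap. Reports the fold enrichment (observed over null mean) and
#' the resampling standard error.
#'
#' @param dynamic_genes,coloc_genes Character vectors, both subsets of
#'   `universe`.
#' @param universe Character vector of all eligible genes.
#' @param rounds Number of resampling rounds (default 100).
#' @param seed Integer seed for the resampling.
#' @return Object of class `enrichment_result`: observed count, null mean
#'   and SE, fold enrichment.
#' @export
coloc_enrichment <- function(dynamic_genes, coloc_genes, universe,
                             rounds = 100, seed = 1) {
  dynamic_genes <- unique(dynamic_genes); coloc_genes <- unique(coloc_genes)
  if (!all(dynamic_genes %in% universe) || !all(coloc_genes %in% universe))
    stop("gene sets must be subsets of the universe", call. = FALSE)
  d <- length(dynamic_genes)
  if (d > length(universe)) stop("sample size exceeds universe", call. = FALSE)
  observed <- length(intersect(dynamic_genes, coloc_genes))
  set.seed(seed)
  null <- replicate(rounds,
                    length(intersect(sample(universe, d), coloc_genes)))
  structure(list(observed = observed, null_mean = mean(null),
                 null_se = stats::sd(null) / sqrt(rounds),
                 null_sd = stats::sd(null),
                 fold = if (mean(null) > 0) observed / mean(null) else NA_real_,
                 rounds = rounds),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: observed %d, null %.2f (SE %.2f), fold %.2f [%d rounds]\n",
              x$observed, x$null_mean, x$null_se, x$fold, x$rounds))
  invisible(x)
}
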