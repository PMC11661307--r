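#' Map trans-eQTLs for a candidate variant set
#'
#' Regresses normalized expression on the dosage of each candidate variant
#' with the same covariates as cis mapping (genotype PCs), keeping only
#' variant-gene pairs on different chromosomes or more than `min_distance`
#' from the gene's TSS. Genes with mappability below `min_mappability` are
#' excluded, as are candidate variants inside the configured MHC interval.
#'
#' @param pb Normalized `pseudobulk`.
#' @param genotypes A `genotype_matrix`.
#' @param genes Gene coordinate table (gene, chrom, tss).
#' @param candidates Character vector of candidate variant ids (typically
#'   cis-eSNPs plus GWAS-significant variants); variants absent from the
#'   genotypes are an error.
#' @param min_distance Minimum variant-TSS distance for a trans pair
#'   (default 5 Mb).
#' @param mappability Optional `data.frame` (gene, score) or named vector.
#' @param min_mappability Genes below this score are excluded (default 0.8).
#' @param mhc Optional MHC interval as `"chrom:start-end"` (e.g.
#'   `"chr6:25000000-34000000"`); candidate variants inside it are removed.
#' @param n_pcs,min_donors As in [map_cis()].
#' @return `data.frame` of class `trans_table`: variant, its coordinates,
#'   gene, gene coordinates, cell_type, beta, se, stat, p.
#' @export
map_trans <- function(pb, genotypes, genes, candidates, min_distance = 5e6,
                      mappability = NULL, min_mappability = 0.8, mhc = NULL,
                      n_pcs = 5, min_donors = 30) {
  stopifnot(inherits(pb, "pseudobulk"), !is.null(pb$residuals))
  v <- genotypes$variants
  missing <- setdiff(candidates, v$variant)
  if (length(missing))
    stop("candidate variant(s) absent from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  if (!is.null(mhc)) {
    iv <- parse_interval(mhc)
    vv <- v[match(candidates, v$variant), ]
    inside <- vv$chrom == iv$chrom & vv$pos >= iv$start & vv$pos <= iv$end
    candidates <- candidates[!inside]
  }
  keep_genes <- genes$gene
  if (!is.null(mappability)) {
    mp <- if (is.data.frame(mappability))
      structure(mappability$score, names = mappability$gene) else mappability
    sc <- mp[keep_genes]
    keep_genes <- keep_genes[!is.na(sc) & sc >= min_mappability]
  }
  vv <- v[match(candidates, v$variant), ]

  out <- list()
  for (ct in pb$cell_types) {
    r <- pb$residuals[[ct]]
    r <- r[rownames(r) %in% keep_genes, , drop = FALSE]
    donors <- colnames(r)
    n <- length(donors)
    if (n < min_donors || !nrow(r)) next
    G <- genotypes$dosage[donors, candidates, drop = FALSE]
    X <- cbind(1, genotypes$pcs[donors, seq_len(min(n_pcs, ncol(genotypes$pcs))),
                                drop = FALSE])
    qrX <- qr(X)
    df <- n - qrX$rank - 1
    Gr <- qr.resid(qrX, G)
    gg <- colSums(Gr^2)
    poly <- gg > 1e-10
    Yr <- qr.resid(qrX, t(r))
    sy <- colSums(Yr^2)
    Bn <- crossprod(Gr, Yr)                       # variants x genes
    gmap <- genes[match(colnames(Yr), genes$gene), ]
    for (vi in which(poly)) {
      far <- gmap$chrom != vv$chrom[vi] | abs(gmap$tss - vv$pos[vi]) > min_distance
      if (!any(far)) next
      b <- Bn[vi, far] / gg[vi]
      rss <- sy[far] - b^2 * gg[vi]
      se <- sqrt(pmax(rss, 0) / df / gg[vi])
      tv <- b / se
      out[[length(out) + 1]] <- data.frame(
        variant = vv$variant[vi], chrom = vv$chrom[vi], pos = vv$pos[vi],
        gene = gmap$gene[far], gene_chrom = gmap$chrom[far],
        tss = gmap$tss[far], cell_type = ct,
        beta = b, se = se, stat = tv, p = 2 * pt(-abs(tv), df),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("trans_table", "data.frame")
  tab
}

parse_interval <- function(x) {
  if (is.list(x)) return(x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("interval must look like 'chr6:25000000-34000000'",
                           call. = FALSE)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Sidak correction for the minimum of k tests
#'
#' Returns \eqn{1 - (1 - \min(p))^k}, computed via `log1p`/`expm1` so that
#' very small minima remain accurate.
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]}.
#' @param k Effective number of tests (default 1e5).
#' @return The Sidak-corrected p-value.
#' @export
sidak_correct <- function(p, k = 1e5) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  -expm1(k * log1p(-min(p)))
}

#' Study-wide Benjamini-Hochberg q-values
#'
#' Applies BH correction across the pooled Sidak-corrected p-values from all
#' genes and cell types.
#'
#' @param p Numeric vector of (Sidak-corrected) p-values.
#' @return Vector of q-values.
#' @export
study_fdr <- function(p) p.adjust(p, method = "BH")

#' Two-stage significance for trans-eQTLs
#'
#' Collapses the trans table to one Sidak-corrected p-value per (gene, cell
#' type) using [sidak_correct()] with `k` tests, then applies study-wide BH
#' across all genes and cell types.
#'
#' @param tab A `trans_table` from [map_trans()].
#' @param k Sidak test count (default 1e5, independent of the actual number
#'   of variants tested).
#' @param fdr Study-wide FDR threshold.
#' @return `data.frame`: gene, cell_type, lead variant, min p, p_sidak, q,
#'   significant.
#' @export
trans_significance <- function(tab, k = 1e5, fdr = 0.05) {
  sp <- split(seq_len(nrow(tab)), list(tab$gene, tab$cell_type), drop = TRUE)
  rows <- lapply(sp, function(i) {
    j <- i[order(tab$p[i], tab$pos[i])][1]
    data.frame(gene = tab$gene[j], cell_type = tab$cell_type[j],
               variant = tab$variant[j], p_min = tab$p[j],
               beta = tab$beta[j], se = tab$se[j],
               p_sidak = sidak_correct(tab$p[i], k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- study_fdr(out$p_sidak)
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}

#' Identify trans-regulatory hubs
#'
#' Groups study-wide significant trans pairs by (variant, cell type) and
#' reports variants associated with at least `min_targets` target genes.
#'
#' @param results `data.frame` of significant trans pairs with columns
#'   `variant`, `cell_type`, `gene` (e.g. the significant rows of
#'   [trans_significance()]).
#' @param min_targets Minimum number of target genes (default 3).
#' @return `data.frame`: variant, cell_type, n_targets, comma-separated
#'   target genes.
#' @export
find_hubs <- function(results, min_targets = 3) {
  sp <- split(results$gene, list(results$variant, results$cell_type), drop = TRUE)
  hubs <- Filter(function(g) length(unique(g)) >= min_targets, sp)
  if (!length(hubs))
    return(data.frame(variant = character(0), cell_type = character(0),
                      n_targets = integer(0), targets = character(0),
                      stringsAsFactors = FALSE))
  keys <- strsplit(names(hubs), ".", fixed = TRUE)
  data.frame(
    variant = vapply(keys, `[`, "", 1),
    cell_type = vapply(keys, `[`, "", 2),
    n_targets = vapply(hubs, function(g) length(unique(g)), integer(1)),
    targets = vapply(hubs, function(g) paste(sort(unique(g)), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of the dosage vectors in the study cohort;
#' invariant to allele coding flips.
#'
#' @param genotypes A `genotype_matrix`.
#' @param v1,v2 Variant identifiers.
#' @return r-squared in \eqn{[0, 1]}.
#' @export
ld_r2 <- function(genotypes, v1, v2) {
  g1 <- genotypes$dosage[, v1]; g2 <- genotypes$dosage[, v2]
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    stop("monomorphic variant", call. = FALSE)
  stats::cor(g1, g2)^2
}

#' Sobel test for an indirect (product-of-coefficients) effect
#'
#' Indirect effect \eqn{a b} with standard error
#' \eqn{\sqrt{b^2 SE_a^2 + a^2 SE_b^2}} and normal-theory two-sided p-value.
#'
#' @param a,se_a Effect of the variant on the mediator and its SE.
#' @param b,se_b Effect of the mediator on the outcome (adjusted for the
#'   variant) and its SE.
#' @return Named vector: indirect, se, z, p.
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  a <- as.numeric(a); se_a <- as.numeric(se_a)
  b <- as.numeric(b); se_b <- as.numeric(se_b)
  ind <- a * b
  se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  z <- ind / se
  c(indirect = ind, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

# OLS coefficient and SE of column `term` of design X for response y
ols_term <- function(y, X, term) {
  qx <- qr(X)
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - qx$rank
  XtXi <- chol2inv(qr.R(qx))
  se <- sqrt(sum(res^2) / df * diag(XtXi))
  i <- match(term, colnames(X))
  c(estimate = unname(cf[i]), se = unname(se[i]), df = df)
}

#' Cis-mediation analysis of trans-eQTL signals
#'
#' For each significant trans pair (variant s, trans gene t, cell type),
#' candidate cis mediators are genes whose lead cis variant lies within
#' `window_bp` of s and is in high LD with it (\eqn{r^2 \ge} `ld_min`,
#' computed from the study genotypes). The indirect effect is estimated by
#' the product of coefficients: a = effect of s on the mediator's
#' expression, b = effect of the mediator's expression on the trans gene
#' adjusting for s (both with genotype-PC covariates), with Sobel standard
#' error \eqn{\sqrt{b^2 SE_a^2 + a^2 SE_b^2}}. BH correction is applied
#' across all mediation tests, and Storey's \eqn{\pi_1} over the mediation
#' p-values estimates the fraction of trans signals with cis mediation.
#'
#' @param trans_sig Significant trans pairs (gene, cell_type, variant), e.g.
#'   significant rows of [trans_significance()].
#' @param cis_leads Cis lead table with columns gene, cell_type, variant
#'   (e.g. from [egene_calling()] restricted to eGenes).
#' @param genotypes A `genotype_matrix`.
#' @param pb Normalized `pseudobulk`.
#' @param ld_min Minimum LD r-squared between the trans-eSNP and the
#'   mediator's lead cis variant (default 0.75).
#' @param window_bp Maximum distance between the trans-eSNP and the
#'   mediator's lead variant (default 1 Mb).
#' @param n_pcs Genotype PCs used as covariates.
#' @param fdr BH threshold for significant mediation.
#' @return Object of class `mediation_result`: per-test data.frame (trans
#'   SNP, mediator, trans gene, a, b, indirect effect, Sobel SE, z, p, q,
#'   proportion mediated, LD r2) with `pi1` attached.
#' @export
mediate <- function(trans_sig, cis_leads, genotypes, pb, ld_min = 0.75,
                    window_bp = 1e6, n_pcs = 5, fdr = 0.05) {
  v <- genotypes$variants
  rows <- list()
  for (i in seq_len(nrow(trans_sig))) {
    s <- trans_sig$variant[i]; tg <- trans_sig$gene[i]; ct <- trans_sig$cell_type[i]
    sv <- v[match(s, v$variant), ]
    cand <- cis_leads[cis_leads$cell_type == ct & cis_leads$gene != tg, , drop = FALSE]
    if (!nrow(cand)) next
    cv <- v[match(cand$variant, v$variant), ]
    near <- cv$chrom == sv$chrom & abs(cv$pos - sv$pos) <= window_bp
    cand <- cand[near, , drop = FALSE]
    if (!nrow(cand)) next
    r <- pb$residuals[[ct]]
    donors <- colnames(r)
    pcs <- genotypes$pcs[donors, seq_len(min(n_pcs, ncol(genotypes$pcs))), drop = FALSE]
    gs <- genotypes$dosage[donors, s]
    for (j in seq_len(nrow(cand))) {
      r2 <- tryCatch(ld_r2(genotypes, s, cand$variant[j]), error = function(e) 0)
      if (r2 < ld_min) next
      med <- cand$gene[j]
      if (!med %in% rownames(r) || !tg %in% rownames(r)) next
      Xa <- cbind(snp = gs, 1, pcs)
      a_fit <- ols_term(r[med, ], Xa, "snp")
      Xb <- cbind(med = r[med, ], snp = gs, 1, pcs)
      b_fit <- ols_term(r[tg, ], Xb, "med")
      sb <- sobel_test(a_fit["estimate"], a_fit["se"],
                       b_fit["estimate"], b_fit["se"])
      ind <- sb["indirect"]; se <- sb["se"]; z <- sb["z"]
      total_fit <- ols_term(r[tg, ], Xa, "snp")
      rows[[length(rows) + 1]] <- data.frame(
        trans_snp = s, mediator = med, trans_gene = tg, cell_type = ct,
        ld_r2 = r2,
        a = unname(a_fit["estimate"]), se_a = unname(a_fit["se"]),
        b = unname(b_fit["estimate"]), se_b = unname(b_fit["se"]),
        indirect = unname(ind), sobel_se = unname(se), z = unname(z),
        p = unname(2 * pnorm(-abs(z))),
        total = unname(total_fit["estimate"]),
        prop_mediated = unname(ind / total_fit["estimate"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame()
    attr(out, "pi1") <- NA_real_
  } else {
    out$q <- p.adjust(out$p, method = "BH")
    out$significant <- out$q <= fdr
    attr(out, "pi1") <- if (sum(is.finite(out$p)) >= 2) 1 - storey_pi0(out$p)
                        else NA_real_
    rownames(out) <- NULL
  }
  class(out) <- c("mediation_result", "data.frame")
  out
}
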