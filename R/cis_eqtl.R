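#' Map cis-eQTLs per cell type
#'
#' For every gene and every polymorphic variant within `window_bp` of the
#' gene's TSS, regresses normalized expression residuals on allele dosage
#' with genotype principal components (population-structure adjustment) and
#' optional hidden expression factors as covariates. P-values are two-sided
#' t-tests on the dosage coefficient.
#'
#' @param pb Normalized `pseudobulk` (see [pb_normalize()]).
#' @param genotypes A `genotype_matrix`.
#' @param genes Gene coordinate table with columns `gene`, `chrom`, `tss`.
#' @param window_bp Cis window half-width around the TSS (default 1 Mb).
#' @param n_pcs Number of genotype PCs included as covariates.
#' @param factors Optional named list (per cell type) of donor-indexed
#'   hidden-factor matrices, as produced inside [hidden_factor_sweep()].
#' @param min_donors Cell types with fewer donors are skipped.
#' @return `data.frame` of class `eqtl_table`: gene, variant, chrom, pos,
#'   cell_type, beta, se, stat, p, maf, n, dist (variant minus TSS).
#' @export
map_cis <- function(pb, genotypes, genes, window_bp = 1e6, n_pcs = 5,
                    factors = NULL, min_donors = 30) {
  stopifnot(inherits(pb, "pseudobulk"), inherits(genotypes, "genotype_matrix"))
  if (is.null(pb$residuals))
    stop("pseudobulk must be normalized first (pb_normalize)", call. = FALSE)
  v <- genotypes$variants
  out <- vector("list", length(pb$cell_types))
  names(out) <- pb$cell_types
  for (ct in pb$cell_types) {
    r <- pb$residuals[[ct]]
    donors <- colnames(r)
    n <- length(donors)
    if (n < min_donors) next
    G <- genotypes$dosage[donors, , drop = FALSE]
    X <- cbind(1, genotypes$pcs[donors, seq_len(min(n_pcs, ncol(genotypes$pcs))),
                                drop = FALSE])
    if (!is.null(factors) && !is.null(factors[[ct]]))
      X <- cbind(X, factors[[ct]][donors, , drop = FALSE])
    qrX <- qr(X)
    df <- n - qrX$rank - 1
    if (df < 3) next
    Gr <- qr.resid(qrX, G)
    gg <- colSums(Gr^2)
    poly <- matrixStats_colVars(G) > 0 & gg > 1e-10
    maf <- colMeans(G) / 2
    maf <- pmin(maf, 1 - maf)
    Yr <- qr.resid(qrX, t(r))

    rows <- vector("list", nrow(r))
    gmap <- genes[match(rownames(r), genes$gene), , drop = FALSE]
    for (gi in seq_len(nrow(r))) {
      if (is.na(gmap$gene[gi])) next
      cis <- which(v$chrom == gmap$chrom[gi] &
                     abs(v$pos - gmap$tss[gi]) <= window_bp & poly)
      if (!length(cis)) next
      y <- Yr[, gi]
      b <- as.vector(crossprod(Gr[, cis, drop = FALSE], y)) / gg[cis]
      rss <- sum(y^2) - b^2 * gg[cis]
      se <- sqrt(pmax(rss, 0) / df / gg[cis])
      tval <- b / se
      rows[[gi]] <- data.frame(
        gene = gmap$gene[gi], variant = v$variant[cis], chrom = v$chrom[cis],
        pos = v$pos[cis], cell_type = ct, beta = b, se = se, stat = tval,
        p = 2 * pt(-abs(tval), df), maf = maf[cis], n = n,
        dist = v$pos[cis] - gmap$tss[gi], stringsAsFactors = FALSE
      )
    }
    out[[ct]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("eqtl_table", "data.frame")
  tab
}

# column variances of a dense matrix without matrixStats
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

#' Lead variant per gene and cell type
#'
#' Smallest p-value per (gene, cell type); ties break to the smaller genomic
#' position.
#'
#' @param table An `eqtl_table`.
#' @return Subset of `table` with one row per (gene, cell type).
#' @export
lead_variants <- function(table) {
  ord <- order(table$gene, table$cell_type, table$p, table$pos)
  t2 <- table[ord, , drop = FALSE]
  keep <- !duplicated(t2[, c("gene", "cell_type")])
  out <- t2[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call eGenes with gene-level Bonferroni and across-gene BH correction
#'
#' The lead p-value of each gene is Bonferroni-adjusted by the number of cis
#' variants tested for the gene, then Benjamini-Hochberg is applied across
#' genes within each cell type. Genes with q below `fdr` are eGenes.
#'
#' @param table An `eqtl_table`.
#' @param fdr FDR threshold (default 0.05).
#' @return `data.frame`: gene, cell_type, lead variant and statistics,
#'   n_variants, p_bonf, q, egene.
#' @export
egene_calling <- function(table, fdr = 0.05) {
  if (is.null(table) || nrow(table) == 0) stop("empty eQTL table", call. = FALSE)
  nv <- stats::aggregate(list(n_variants = table$p),
                         by = table[, c("gene", "cell_type")], FUN = length)
  leads <- lead_variants(table)
  leads <- merge(leads, nv, by = c("gene", "cell_type"), sort = FALSE)
  leads$p_bonf <- pmin(1, leads$p * leads$n_variants)
  leads$q <- NA_real_
  for (ct in unique(leads$cell_type)) {
    sel <- leads$cell_type == ct
    leads$q[sel] <- p.adjust(leads$p_bonf[sel], method = "BH")
  }
  leads$egene <- leads$q <= fdr
  leads <- leads[order(leads$cell_type, leads$gene), , drop = FALSE]
  rownames(leads) <- NULL
  leads
}
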