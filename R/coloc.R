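#' Harmonize two summary-statistics panels onto shared variants
#'
#' Intersects the two panels on chromosome and position, flips the sign of
#' the second trait's effect where reference and alternate alleles are
#' swapped, and drops strand-ambiguous (A/T or C/G) variants and variants
#' whose alleles cannot be reconciled.
#'
#' @param a,b `data.frame`s with columns `chrom`, `pos`, `ref`, `alt`,
#'   `beta`, `se` (class `summary_stats` or compatible).
#' @return List with harmonized `a` and `b` (same row order), the number of
#'   sign flips, and the dropped variant keys.
#' @export
harmonize <- function(a, b) {
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  shared <- intersect(key(a), key(b))
  if (!length(shared)) stop("no overlapping variants between the two panels",
                            call. = FALSE)
  a2 <- a[match(shared, key(a)), , drop = FALSE]
  b2 <- b[match(shared, key(b)), , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- comp[a2$ref] == a2$alt
  same <- a2$ref == b2$ref & a2$alt == b2$alt
  swapped <- a2$ref == b2$alt & a2$alt == b2$ref
  keep <- !ambiguous & (same | swapped)
  dropped <- shared[!keep]
  a2 <- a2[keep, , drop = FALSE]
  b2 <- b2[keep, , drop = FALSE]
  flip <- swapped[keep]
  b2$beta[flip] <- -b2$beta[flip]
  rownames(a2) <- rownames(b2) <- NULL
  list(a = a2, b = b2, n_flipped = sum(flip), dropped = dropped)
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Bayesian colocalization of two association signals
#'
#' Computes per-variant Wakefield log approximate Bayes factors for each
#' trait (prior effect SD `prior_sd` on standardized traits) and evaluates
#' the posterior probabilities of the five hypotheses of the pairwise
#' colocalization model: H0 no association, H1/H2 association with one
#' trait only, H3 two distinct causal variants, H4 one shared causal
#' variant. Sums over variant configurations use log-sum-exp so that very
#' strong signals (|z| well above 30) do not overflow.
#'
#' @param a,b Harmonized summary statistics (equal length, shared variants
#'   in the same order; see [harmonize()]), with `beta` and `se` columns.
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait 1
#'   only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd Prior SD of the causal effect (default 0.15; traits are
#'   assumed variance-standardized).
#' @return Object of class `coloc_result`: posterior probabilities
#'   `pp` (PP0..PP4), per-variant H4 weights, number of variants, and a
#'   `degenerate` flag when fewer than 2 variants are available (H3 is then
#'   undefined and set to 0).
#' @export
coloc_abf <- function(a, b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, prior_sd = 0.15) {
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  W <- prior_sd^2
  labf <- function(beta, se) {
    V <- se^2
    0.5 * log(V / (V + W)) + 0.5 * (beta / se)^2 * W / (V + W)
  }
  la <- labf(a$beta, a$se)
  lb <- labf(b$beta, b$se)
  l1 <- log_sum_exp(la)
  l2 <- log_sum_exp(lb)
  l4 <- log_sum_exp(la + lb)
  # sum over ordered pairs v != w equals (sum_a)(sum_b) - sum_v a_v b_v
  l3 <- if (n < 2) -Inf else {
    d <- l4 - (l1 + l2)
    if (d >= 0) -Inf else l1 + l2 + log1p(-exp(d))
  }
  lh <- c(h0 = 0,
          h1 = log(p1) + l1,
          h2 = log(p2) + l2,
          h3 = log(p1) + log(p2) + l3,
          h4 = log(p12) + l4)
  pp <- exp(lh - log_sum_exp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  wts <- exp(la + lb - l4)
  out <- list(pp = pp,
              h4_weights = data.frame(variant = if (!is.null(a$variant)) a$variant
                                      else paste0(a$chrom, ":", a$pos),
                                      weight = wts, stringsAsFactors = FALSE),
              nsnps = n, degenerate = n < 2)
  class(out) <- "coloc_result"
  out
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants%s\n", x$nsnps,
              if (x$degenerate) " (degenerate: < 2 variants)" else ""))
  print(round(x$pp, 4))
  invisible(x)
}

#' Colocalize every gene's cis signal with a GWAS trait
#'
#' Runs [coloc_abf()] per gene and cell type over the gene's cis window,
#' harmonizing the eQTL and GWAS panels first.
#'
#' @param eqtls An `eqtl_table` from [map_cis()].
#' @param gwas GWAS `summary_stats`.
#' @param genes Optional character vector of genes to scan (default: all).
#' @param ... Passed to [coloc_abf()] (priors, prior_sd).
#' @return `data.frame`: gene, cell_type, nsnps, PP0..PP4, top H4 variant
#'   and its weight.
#' @export
coloc_scan <- function(eqtls, gwas, genes = NULL, ...) {
  if (is.null(genes)) genes <- unique(eqtls$gene)
  rows <- list()
  for (g in genes) {
    for (ct in unique(eqtls$cell_type[eqtls$gene == g])) {
      e <- eqtls[eqtls$gene == g & eqtls$cell_type == ct, , drop = FALSE]
      if (!nrow(e)) next
      e$ref <- "A"; e$alt <- "G"
      h <- tryCatch(harmonize(e, gwas), error = function(err) NULL)
      if (is.null(h) || nrow(h$a) < 2) next
      cr <- coloc_abf(h$a, h$b, ...)
      top <- which.max(cr$h4_weights$weight)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, cell_type = ct, nsnps = cr$nsnps, t(cr$pp),
        top_variant = cr$h4_weights$variant[top],
        top_weight = cr$h4_weights$weight[top],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
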