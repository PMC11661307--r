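#' Fine-map cis associations under a single-causal-variant model
#'
#' Computes Wakefield approximate Bayes factors per variant,
#' \deqn{\log \mathrm{ABF}_v = \tfrac12 \log\frac{V_v}{V_v + W}
#'   + \tfrac12 z_v^2 \frac{W}{V_v + W}}
#' with \eqn{V = \mathrm{SE}^2}, \eqn{W = \mathrm{prior\_sd}^2} and
#' \eqn{z = \hat\beta/\mathrm{SE}}. Under the assumption of exactly one
#' causal variant per gene, posterior inclusion probabilities are the
#' normalized ABFs, so they sum to 1 within each (gene, cell type). The 95%
#' credible set is the smallest prefix of PIP-sorted variants whose
#' cumulative PIP reaches 0.95.
#'
#' @param table An `eqtl_table` (any subset with beta/se columns).
#' @param prior_sd Prior SD of the causal effect on standardized expression
#'   (default 0.15).
#' @param coverage Credible-set coverage (default 0.95).
#' @return `data.frame` of class `finemap_result`: gene, cell_type, variant,
#'   chrom, pos, labf, pip, cs.
#' @export
finemap_abf <- function(table, prior_sd = 0.15, coverage = 0.95) {
  stopifnot(nrow(table) > 0)
  if (!all(is.finite(table$se)) || any(table$se <= 0))
    stop("all standard errors must be finite and positive", call. = FALSE)
  W <- prior_sd^2
  V <- table$se^2
  z <- table$beta / table$se
  labf <- 0.5 * log(V / (V + W)) + 0.5 * z^2 * W / (V + W)
  key <- interaction(table$gene, table$cell_type, drop = TRUE)
  pip <- numeric(nrow(table)); cs <- logical(nrow(table))
  for (k in levels(key)) {
    i <- which(key == k)
    l <- labf[i]
    p <- exp(l - max(l)); p <- p / sum(p)
    pip[i] <- p
    o <- order(p, decreasing = TRUE)
    m <- which(cumsum(p[o]) >= coverage)[1]
    cs[i[o[seq_len(m)]]] <- TRUE
  }
  out <- data.frame(gene = table$gene, cell_type = table$cell_type,
                    variant = table$variant, chrom = table$chrom,
                    pos = table$pos, labf = labf, pip = pip, cs = cs,
                    stringsAsFactors = FALSE)
  class(out) <- c("finemap_result", "data.frame")
  out
}

#' Per-variant MaxCPP annotation
#'
#' Each variant receives the maximum posterior inclusion probability it
#' attains across all genes for which it lies in the 95% credible set;
#' variants in no credible set receive 0.
#'
#' @param fm A `finemap_result` from [finemap_abf()].
#' @return `data.frame`: variant, maxcpp.
#' @export
max_cpp <- function(fm) {
  val <- ifelse(fm$cs, fm$pip, 0)
  agg <- tapply(val, fm$variant, max)
  data.frame(variant = names(agg), maxcpp = as.vector(agg),
             stringsAsFactors = FALSE)
}
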