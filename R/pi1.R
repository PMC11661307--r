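#' Storey pi0 estimate from a vector of p-values
#'
#' Estimates the proportion of true nulls by the Storey method: for a grid of
#' tuning values lambda, \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} /
#' (m (1 - \lambda))}, smoothed with a natural cubic spline (3 df) and
#' evaluated at the largest lambda.
#'
#' @param p Numeric p-values in (0, 1].
#' @param lambda Tuning grid (default `seq(0.05, 0.95, 0.05)`).
#' @return Estimated pi0, clamped to (0, 1].
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  p <- p[is.finite(p)]
  if (!length(p)) stop("no finite p-values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Replication rate pi1 of discovery eQTLs in a second dataset
#'
#' Matches the discovery lead variants to the replication table by gene,
#' variant and cell type, extracts the replication p-values, and reports
#' \eqn{\pi_1 = 1 - \hat\pi_0}: the estimated fraction of discovery signals
#' for which the null is rejected in the replication data.
#'
#' @param discovery An `eqtl_table` (its lead variants are used) or the
#'   output of [lead_variants()].
#' @param replication An `eqtl_table` from the replication dataset.
#' @return List with `pi1`, `n_pairs`, and the matched p-values.
#' @export
pi1_replication <- function(discovery, replication) {
  leads <- lead_variants(discovery)
  key <- function(d) paste(d$gene, d$variant, d$cell_type, sep = "|")
  idx <- match(key(leads), key(replication))
  p_rep <- replication$p[idx[!is.na(idx)]]
  if (length(p_rep) < 50)
    warning("fewer than 50 matched discovery/replication pairs; pi1 is unstable",
            call. = FALSE)
  list(pi1 = 1 - storey_pi0(p_rep), n_pairs = length(p_rep), p_replication = p_rep)
}
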