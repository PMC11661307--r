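#' Assemble the lead-variant effect panel across cell types
#'
#' For each gene, selects the variant with the smallest p-value across all
#' cell types and collects that variant's coefficient estimate and standard
#' error in every cell type. Entries missing in a cell type (gene not tested
#' there) are encoded with coefficient 0 and standard error `missing_se`
#' (default 1e6), so they carry essentially no likelihood information.
#'
#' @param table An `eqtl_table`.
#' @param genes Optional character vector restricting the genes (e.g. eGenes).
#' @param missing_se Standard error assigned to missing entries.
#' @return Object of class `effect_panel`: list with matrices `beta` and `se`
#'   (genes x cell types), logical `missing` mask, and the chosen `variant`
#'   per gene.
#' @export
effect_panel <- function(table, genes = NULL, missing_se = 1e6) {
  if (is.null(genes)) genes <- unique(table$gene)
  cts <- sort(unique(table$cell_type))
  tab <- table[table$gene %in% genes, , drop = FALSE]
  ord <- order(tab$gene, tab$p, tab$pos)
  best <- tab[ord, ][!duplicated(tab$gene[ord]), c("gene", "variant")]
  beta <- matrix(0, length(genes), length(cts), dimnames = list(genes, cts))
  se <- matrix(missing_se, length(genes), length(cts), dimnames = list(genes, cts))
  key <- paste(tab$gene, tab$variant, tab$cell_type, sep = "|")
  for (ct in cts) {
    idx <- match(paste(best$gene, best$variant, ct, sep = "|"), key)
    hit <- !is.na(idx)
    beta[match(best$gene[hit], genes), ct] <- tab$beta[idx[hit]]
    se[match(best$gene[hit], genes), ct] <- tab$se[idx[hit]]
  }
  structure(list(beta = beta, se = se, missing = se >= missing_se,
                 variant = structure(best$variant, names = best$gene)),
            class = "effect_panel")
}

#' @export
print.effect_panel <- function(x, ...) {
  cat(sprintf("Effect panel: %d genes x %d cell types (%d missing entries)\n",
              nrow(x$beta), ncol(x$beta), sum(x$missing)))
  invisible(x)
}

# Canonical covariance templates: identity (independent effects), one
# singleton per cell type (effect in a single type), equal effects in all
# types (rank 1), and moderately correlated shared effects.
canonical_covariances <- function(C, het_rho = 0.5) {
  Us <- list(identity = diag(C))
  for (i in seq_len(C)) {
    M <- matrix(0, C, C); M[i, i] <- 1
    Us[[paste0("singleton_", i)]] <- M
  }
  Us$equal <- matrix(1, C, C)
  if (C > 1) Us$het <- het_rho + diag(C) * (1 - het_rho)
  Us
}

#' Fit the empirical-Bayes prior mixture over effect-sharing patterns
#'
#' Maximizes the marginal likelihood
#' \eqn{\prod_j \sum_k w_k\, N(\hat\beta_j; 0, \Sigma_k + S_j)} over mixture
#' weights by EM, where \eqn{S_j} is the diagonal matrix of squared standard
#' errors of gene *j* and the \eqn{\Sigma_k} are canonical covariance
#' templates (null, identity, per-cell-type singletons, equal effects,
#' correlated-shared) expanded over a geometric scale grid. Component
#' likelihoods are fixed given the data, so the EM updates only the weights;
#' a mild null-biased penalty (Dirichlet weight `nullbiased` on the null
#' component) resolves the indistinguishability of the null and
#' vanishing-scale components. The scale grid spans the median observed
#' standard error (effects below the measurement noise are absorbed by the
#' null) up to twice the largest observed effect.
#'
#' @param panel An `effect_panel`; rows may include a random background set
#'   of variant-gene pairs in addition to lead variants (see
#'   [background_panel()]).
#' @param scales Optional numeric vector of component scales (prior effect
#'   SDs); computed from the panel when `NULL`.
#' @param n_scales Number of grid points when `scales` is `NULL`.
#' @param components Covariance templates; defaults to the canonical set.
#' @param nullbiased Dirichlet prior weight on the null component.
#' @param tol EM stops when the penalized log-likelihood gain drops below
#'   this value.
#' @param maxit Maximum EM iterations.
#' @return Object of class `prior_mixture`: covariances `U` (the first is
#'   the null), `weights`, `scales`, and the log-likelihood trace.
#' @export
fit_prior <- function(panel, scales = NULL, n_scales = 8, components = NULL,
                      nullbiased = 10, tol = 1e-6, maxit = 5000) {
  stopifnot(inherits(panel, "effect_panel"))
  B <- panel$beta; S <- panel$se
  C <- ncol(B)
  if (is.null(scales)) {
    obs_se <- S[!panel$missing]
    lo <- stats::median(obs_se)
    hi <- max(2 * max(abs(B[!panel$missing])), lo * 4)
    scales <- exp(seq(log(lo), log(hi), length.out = n_scales))
  }
  if (is.null(components)) components <- canonical_covariances(C)
  for (U in components) {
    ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("component covariance is not positive semidefinite",
                              call. = FALSE)
  }
  U <- list(null = matrix(0, C, C))
  for (s in scales) for (nm in names(components))
    U[[sprintf("%s_s%.4g", nm, s)]] <- s^2 * components[[nm]]

  L <- component_loglik(B, S, U)
  K <- length(U)
  pen <- c(nullbiased, rep(1, K - 1))
  # the component log-likelihoods are fixed, so the EM reduces to two
  # matrix-vector products per iteration on the rescaled likelihood matrix
  mrow <- apply(L, 1, max)
  E <- exp(L - mrow)
  w <- rep(1 / K, K)
  ll_trace <- numeric(0); ll_old <- -Inf
  for (it in seq_len(maxit)) {
    denom <- as.vector(E %*% w)
    ll <- sum(mrow + log(denom)) + sum((pen - 1) * log(pmax(w, 1e-300)))
    if (ll < ll_old - 1e-6) stop("EM log-likelihood decreased", call. = FALSE)
    ll_trace <- c(ll_trace, ll)
    nk <- w * as.vector(crossprod(E, 1 / denom)) + pen - 1
    w <- pmax(nk, 0); w <- w / sum(w)
    if (it > 1 && ll - ll_old < tol) break
    ll_old <- ll
  }
  structure(list(U = U, weights = structure(w, names = names(U)),
                 scales = scales, loglik = ll_trace, iterations = it),
            class = "prior_mixture")
}

# log N(b_j; 0, U_k + diag(se_j^2)) for every gene j and component k.
# Genes sharing an identical SE row share one Cholesky per component, so the
# quadratic forms vectorize over them.
component_loglik <- function(B, S, U) {
  n <- nrow(B); K <- length(U); C <- ncol(B)
  L <- matrix(0, n, K)
  cst <- -0.5 * C * log(2 * pi)
  se_key <- apply(S, 1, paste, collapse = "\r")
  groups <- split(seq_len(n), se_key)
  for (k in seq_len(K)) {
    Uk <- U[[k]]
    for (J in groups) {
      V <- Uk + diag(S[J[1], ]^2, C)
      ch <- chol(V)
      Z <- backsolve(ch, t(B[J, , drop = FALSE]), transpose = TRUE)
      L[J, k] <- cst - sum(log(diag(ch))) - 0.5 * colSums(Z * Z)
    }
  }
  L
}

#' @export
print.prior_mixture <- function(x, ...) {
  cat(sprintf("Prior mixture: %d components, EM converged in %d iterations\n",
              length(x$U), x$iterations))
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[top > 0.01]
  for (nm in names(top)) cat(sprintf("  %-22s %.3f\n", nm, top[nm]))
  invisible(x)
}

#' Sample a random background panel for prior fitting
#'
#' Draws `n` random (gene, variant, cell type)-consistent rows from the eQTL
#' table, one variant per sampled gene, to represent the bulk of
#' variant-trait pairs when estimating the prior mixture.
#'
#' @param table An `eqtl_table`.
#' @param n Number of background variant-gene pairs.
#' @param seed Integer seed.
#' @return An `effect_panel` whose rows are named `gene@variant`.
#' @export
background_panel <- function(table, n = 2000, seed = 1) {
  set.seed(seed)
  pairs <- unique(table[, c("gene", "variant")])
  pick <- pairs[sample.int(nrow(pairs), min(n, nrow(pairs))), , drop = FALSE]
  cts <- sort(unique(table$cell_type))
  key <- paste(table$gene, table$variant, table$cell_type, sep = "|")
  rn <- paste(pick$gene, pick$variant, sep = "@")
  beta <- matrix(0, nrow(pick), length(cts), dimnames = list(rn, cts))
  se <- matrix(1e6, nrow(pick), length(cts), dimnames = list(rn, cts))
  for (ct in cts) {
    idx <- match(paste(pick$gene, pick$variant, ct, sep = "|"), key)
    hit <- !is.na(idx)
    beta[hit, ct] <- table$beta[idx[hit]]
    se[hit, ct] <- table$se[idx[hit]]
  }
  structure(list(beta = beta, se = se, missing = se >= 1e6,
                 variant = structure(pick$variant, names = rn)),
            class = "effect_panel")
}

#' Combine two effect panels by row
#' @param a,b `effect_panel` objects with identical cell types.
#' @return An `effect_panel`.
#' @export
rbind_panels <- function(a, b) {
  stopifnot(identical(colnames(a$beta), colnames(b$beta)))
  structure(list(beta = rbind(a$beta, b$beta), se = rbind(a$se, b$se),
                 missing = rbind(a$missing, b$missing),
                 variant = c(a$variant, b$variant)),
            class = "effect_panel")
}

#' Posterior effects and local false sign rates under the fitted prior
#'
#' For each gene the posterior is a mixture over prior components with
#' responsibilities proportional to \eqn{w_k N(\hat\beta_j; 0, \Sigma_k +
#' S_j)}; each component contributes the conjugate normal posterior
#' \eqn{\mu_k = \Sigma_k (\Sigma_k + S_j)^{-1} \hat\beta_j},
#' \eqn{V_k = \Sigma_k - \Sigma_k (\Sigma_k + S_j)^{-1} \Sigma_k}
#' (valid for singular \eqn{\Sigma_k}; coordinates with zero prior variance
#' carry a point mass at zero). The local false sign rate of entry (i, j) is
#' \eqn{\mathrm{lfsr} = \min[P(\beta \ge 0 \mid \cdot), P(\beta \le 0 \mid
#' \cdot)]} with any point mass at zero counted in both tails, and
#' \eqn{p = 1 - \mathrm{lfsr}} is the probability that the sign of the
#' estimate agrees with the sign of the true effect.
#'
#' @param panel An `effect_panel`.
#' @param prior A `prior_mixture` from [fit_prior()].
#' @return Object of class `posterior_panel`: matrices `mean`, `lfsr` and
#'   `p_sign` (= 1 - lfsr), all genes x cell types.
#' @export
posterior_panel <- function(panel, prior) {
  stopifnot(inherits(panel, "effect_panel"), inherits(prior, "prior_mixture"))
  B <- panel$beta; S <- panel$se
  if (ncol(B) != ncol(prior$U[[1]]))
    stop("panel and prior have different numbers of cell types", call. = FALSE)
  n <- nrow(B); C <- ncol(B); K <- length(prior$U)
  w <- prior$weights
  active <- which(w > 1e-12)
  pmean <- matrix(0, n, C, dimnames = dimnames(B))
  p_neg <- matrix(0, n, C); p_pos <- matrix(0, n, C)
  L <- component_loglik(B, S, prior$U[active])
  lw <- sweep(L, 2, log(w[active]), "+")
  mx <- apply(lw, 1, max)
  R <- exp(lw - mx); R <- R / rowSums(R)

  for (ki in seq_along(active)) {
    Uk <- prior$U[[active[ki]]]
    zero_comp <- all(Uk == 0)
    for (j in seq_len(n)) {
      r <- R[j, ki]
      if (r < 1e-14) { p_neg[j, ] <- p_neg[j, ] + r; p_pos[j, ] <- p_pos[j, ] + r; next }
      if (zero_comp) {
        p_neg[j, ] <- p_neg[j, ] + r
        p_pos[j, ] <- p_pos[j, ] + r
        next
      }
      A <- solve(Uk + diag(S[j, ]^2, C), Uk)        # (U+S)^{-1} U
      mu <- drop(B[j, ] %*% A)
      Vp <- Uk - crossprod(A, Uk)
      sd_k <- sqrt(pmax(diag(Vp), 0))
      pmean[j, ] <- pmean[j, ] + r * mu
      pos_mass <- ifelse(sd_k > 1e-12, pnorm(0, mu, sd_k, lower.tail = FALSE),
                         as.numeric(mu >= 0))
      neg_mass <- ifelse(sd_k > 1e-12, pnorm(0, mu, sd_k),
                         as.numeric(mu <= 0))
      p_neg[j, ] <- p_neg[j, ] + r * neg_mass
      p_pos[j, ] <- p_pos[j, ] + r * pos_mass
    }
  }
  lfsr <- pmin(pmin(p_neg, p_pos), 1)
  dimnames(lfsr) <- dimnames(B)
  structure(list(mean = pmean, lfsr = lfsr, p_sign = 1 - lfsr),
            class = "posterior_panel")
}

#' @export
print.posterior_panel <- function(x, ...) {
  cat(sprintf("Posterior panel: %d genes x %d cell types; median lfsr %.3f\n",
              nrow(x$mean), ncol(x$mean), stats::median(x$lfsr)))
  invisible(x)
}
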