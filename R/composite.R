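#' Composite probability of a cell-type arrangement of eQTL effects
#'
#' Given per-cell-type posterior sign probabilities \eqn{p_i} (1 minus the
#' local false sign rate), the probability that a gene's effect is non-zero
#' in every cell type of `set1` while being zero in every cell type of
#' `set2` is
#' \deqn{\Big[\prod_{i \in \mathrm{set1}} p_i\Big]
#'       \Big[\prod_{i \in \mathrm{set2}} (1 - p_i)\Big],}
#' treating the per-cell-type probabilities as independent. An empty `set1`
#' (or `set2`) contributes an empty product of 1.
#'
#' @param p_row Named numeric vector of probabilities in \eqn{[0, 1]}.
#' @param set1 Cell types required to have a non-zero effect.
#' @param set2 Cell types required to have a zero effect; must be disjoint
#'   from `set1`.
#' @return The composite probability.
#' @export
composite_specific <- function(p_row, set1, set2) {
  if (length(intersect(set1, set2)))
    stop("set1 and set2 must be disjoint", call. = FALSE)
  p1 <- p_row[set1]; p2 <- p_row[set2]
  if (anyNA(p1) || anyNA(p2))
    stop("sets refer to cell types absent from p_row", call. = FALSE)
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  prod(p1) * prod(1 - p2)
}

#' Probability of a non-zero effect in at least one cell type of a set
#'
#' Evaluates \eqn{1 - \prod_{i \in \mathrm{set1}} (1 - p_i)}: the
#' complement of "zero everywhere in the set", used to test for an effect in
#' at least one member of a family of related cell types (e.g. all
#' inhibitory-neuron subclasses).
#'
#' @inheritParams composite_specific
#' @return The at-least-one probability.
#' @export
composite_any <- function(p_row, set1) {
  if (!length(set1)) stop("set1 must be nonempty", call. = FALSE)
  p1 <- p_row[set1]
  if (anyNA(p1)) stop("set1 refers to cell types absent from p_row", call. = FALSE)
  if (any(p1 < 0) || any(p1 > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  1 - prod(1 - p1)
}

#' Scan genes for cell-type-specific regulatory effects
#'
#' For every gene, evaluates the composite probability that its effect is
#' specific to each single cell type (non-zero there, zero in all others),
#' and optionally to each named family of cell types (non-zero in at least
#' one member via [composite_any()], zero in all non-members). The best
#' arrangement per gene is reported; genes whose best probability exceeds
#' `threshold` are called specific.
#'
#' @param posterior A `posterior_panel` (see [posterior_panel()]), or a
#'   genes x cell types matrix of sign probabilities.
#' @param groups Optional named list of cell-type families, e.g.
#'   `list(IN = c("IN_A", "IN_B"))`.
#' @param threshold Posterior probability above which a call is made.
#' @return `data.frame` of class `specificity_scan`: gene, best arrangement,
#'   its probability, and the call; the full gene x arrangement probability
#'   matrix is attached as `attr(, "probabilities")`.
#' @export
specificity_scan <- function(posterior, groups = NULL, threshold = 0.5) {
  P <- if (inherits(posterior, "posterior_panel")) posterior$p_sign else posterior
  cts <- colnames(P)
  arr_names <- c(cts, names(groups))
  probs <- matrix(NA_real_, nrow(P), length(arr_names),
                  dimnames = list(rownames(P), arr_names))
  for (j in seq_len(nrow(P))) {
    p <- stats::setNames(as.vector(P[j, , drop = TRUE]), cts)
    for (ct in cts)
      probs[j, ct] <- composite_specific(p, ct, setdiff(cts, ct))
    for (g in names(groups)) {
      inside <- groups[[g]]
      probs[j, g] <- composite_any(p, inside) *
        composite_specific(p, character(0), setdiff(cts, inside))
    }
  }
  best <- max.col(probs, ties.method = "first")
  out <- data.frame(gene = rownames(P),
                    arrangement = arr_names[best],
                    probability = probs[cbind(seq_len(nrow(P)), best)],
                    stringsAsFactors = FALSE)
  out$specific <- out$probability > threshold
  attr(out, "probabilities") <- probs
  class(out) <- c("specificity_scan", "data.frame")
  out
}
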