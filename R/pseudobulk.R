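#' Aggregate nucleus counts to donor-by-cell-type pseudobulk
#'
#' Sums raw counts over all nuclei of the same donor within each cell type.
#' Donors contributing zero nuclei to a cell type are absent from that cell
#' type's matrix (not zero-filled). Donor-level covariates (pool, mean
#' mitochondrial fraction, age, sex, library depth, number of nuclei) are
#' carried alongside each matrix.
#'
#' @param nuclei A `nucleus_table` (see [simulate_nuclei()] or
#'   [read_nucleus_table()]).
#' @param level Label recorded on the result (`"class"` or `"subclass"`);
#'   aggregation always uses the `cell_type` column of the metadata.
#' @param cell_types Optional subset of cell-type labels to aggregate;
#'   unknown labels are an error.
#' @return Object of class `pseudobulk`: per-cell-type list of raw count
#'   matrices (genes x donors), covariate tables, and nuclei counts.
#' @export
pb_aggregate <- function(nuclei, level = c("class", "subclass"), cell_types = NULL) {
  stopifnot(inherits(nuclei, "nucleus_table"))
  level <- match.arg(level)
  meta <- nuclei$meta
  present <- unique(meta$cell_type)
  if (is.null(cell_types)) cell_types <- sort(present)
  unknown <- setdiff(cell_types, present)
  if (length(unknown))
    stop("unknown cell-type label(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  raw <- list(); covars <- list(); n_nuclei <- list()
  for (ct in cell_types) {
    sel <- which(meta$cell_type == ct)
    d <- factor(meta$donor[sel])
    # indicator matrix: nuclei x donors; counts %*% indicator sums per donor
    ind <- Matrix::sparseMatrix(i = seq_along(sel), j = as.integer(d),
                                x = 1, dims = c(length(sel), nlevels(d)))
    m <- as.matrix(nuclei$counts[, sel, drop = FALSE] %*% ind)
    colnames(m) <- levels(d)
    raw[[ct]] <- m
    n_nuclei[[ct]] <- table(d)
    first <- sel[!duplicated(meta$donor[sel])]
    cv <- data.frame(donor = meta$donor[first],
                     pool = meta$pool[first],
                     age = meta$age[first],
                     sex = meta$sex[first],
                     stringsAsFactors = FALSE)
    cv <- cv[match(levels(d), cv$donor), , drop = FALSE]
    cv$mito <- as.vector(tapply(meta$mito_frac[sel], d, mean))
    cv$depth <- colSums(m)
    cv$n_nuclei <- as.vector(n_nuclei[[ct]])
    rownames(cv) <- NULL
    covars[[ct]] <- cv
  }
  structure(list(level = level, cell_types = cell_types, raw = raw,
                 covariates = covars, n_nuclei = n_nuclei,
                 genes = nuclei$genes, residuals = NULL),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("Pseudobulk (%s level): %d cell types, %d genes\n",
              x$level, length(x$cell_types), nrow(x$raw[[1]])))
  for (ct in x$cell_types)
    cat(sprintf("  %s: %d donors%s\n", ct, ncol(x$raw[[ct]]),
                if (!is.null(x$residuals)) sprintf(", %d genes normalized",
                                                   nrow(x$residuals[[ct]])) else ""))
  invisible(x)
}

#' Normalize pseudobulk expression to covariate-adjusted Pearson residuals
#'
#' Per gene and cell type, fits a Poisson working model with a log library
#' depth offset and the requested donor covariates, and emits Pearson
#' residuals (observed minus fitted, divided by the fitted standard
#' deviation). Residuals are then standardized to unit variance per gene so
#' that downstream effect sizes are on the standardized-expression scale.
#' Genes expressed (nonzero) in fewer than `min_donors` donors in a cell type
#' are excluded from that cell type; constant or duplicate covariate columns
#' are dropped with a warning.
#'
#' @param pb A `pseudobulk` from [pb_aggregate()].
#' @param covariates Character vector of covariate column names from the
#'   per-cell-type covariate tables (default pool and mitochondrial fraction).
#' @param min_donors Minimum number of donors with nonzero counts.
#' @return The `pseudobulk` with a `residuals` entry (genes x donors matrix
#'   per cell type).
#' @export
pb_normalize <- function(pb, covariates = c("pool", "mito"), min_donors = 20) {
  stopifnot(inherits(pb, "pseudobulk"))
  res <- list()
  for (ct in pb$cell_types) {
    m <- pb$raw[[ct]]
    cv <- pb$covariates[[ct]]
    keep <- rowSums(m > 0) >= min_donors
    m <- m[keep, , drop = FALSE]
    X <- stats::model.matrix(~1, data = cv)
    for (v in covariates) {
      col <- cv[[v]]
      if (is.null(col)) stop("covariate '", v, "' absent for cell type ", ct, call. = FALSE)
      mm <- if (is.character(col) || is.factor(col)) {
        stats::model.matrix(~f, data = data.frame(f = factor(col)))[, -1, drop = FALSE]
      } else matrix(col, ncol = 1, dimnames = list(NULL, v))
      X <- cbind(X, mm)
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
      warning("dropping constant/duplicate covariate column(s) in ", ct, ": ",
              paste(colnames(X)[drop], collapse = ", "), call. = FALSE)
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
    off <- log(pmax(cv$depth, 1))
    r <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    for (g in seq_len(nrow(m))) {
      fit <- suppressWarnings(
        stats::glm.fit(X, m[g, ], offset = off, family = stats::poisson())
      )
      mu <- fit$fitted.values
      r[g, ] <- (m[g, ] - mu) / sqrt(pmax(mu, 1e-8))
    }
    sds <- apply(r, 1, stats::sd)
    ok <- is.finite(sds) & sds > 0
    r <- r[ok, , drop = FALSE] / sds[ok]
    res[[ct]] <- r
  }
  pb$residuals <- res
  pb$normalization <- list(covariates = covariates, min_donors = min_donors)
  pb
}

#' Select the number of hidden expression factors by eGene yield
#'
#' Computes expression principal components from the normalized residuals of
#' each cell type, then repeats cis-eQTL mapping with the top `f` components
#' included as covariates for every `f` in `grid`, counting eGenes at each
#' setting. The grid value with the most eGenes (summed over cell types) is
#' selected; ties break to the smallest count.
#'
#' @param pb Normalized `pseudobulk` (see [pb_normalize()]).
#' @param genotypes A `genotype_matrix`.
#' @param genes Gene coordinate table (gene, chrom, tss).
#' @param grid Integer vector of factor counts to try.
#' @param ... Passed to [map_cis()] (window, PCs, thresholds).
#' @return Object of class `factor_sweep`: data.frame of grid and eGene
#'   counts, with the selected count in `attr(, "selected")` and as
#'   `$selected`.
#' @export
hidden_factor_sweep <- function(pb, genotypes, genes, grid = seq(0, 20, 5), ...) {
  stopifnot(inherits(pb, "pseudobulk"), !is.null(pb$residuals))
  grid <- sort(unique(as.integer(grid)))
  max_d <- min(vapply(pb$residuals, ncol, integer(1)))
  if (any(grid >= max_d))
    stop("factor counts must be smaller than the number of donors (", max_d, ")",
         call. = FALSE)
  pcs <- lapply(pb$residuals, function(r) {
    s <- svd(scale(t(r), scale = FALSE), nu = min(max(grid), ncol(r) - 1), nv = 0)
    u <- s$u * rep(s$d[seq_len(ncol(s$u))], each = nrow(s$u))
    rownames(u) <- colnames(r)
    u
  })
  counts <- vapply(grid, function(f) {
    fac <- if (f > 0) lapply(pcs, function(u) u[, seq_len(f), drop = FALSE]) else NULL
    tab <- map_cis(pb, genotypes, genes, factors = fac, ...)
    sum(egene_calling(tab)$egene)
  }, integer(1))
  sel <- grid[which.max(counts)]  # which.max takes the first (smallest) on ties
  out <- list(sweep = data.frame(n_factors = grid, n_egenes = counts),
              selected = sel)
  class(out) <- "factor_sweep"
  out
}

#' @export
print.factor_sweep <- function(x, ...) {
  print(x$sweep, row.names = FALSE)
  cat("selected:", x$selected, "factors\n")
  invisible(x)
}
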