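#' Write genotypes to a minimal VCF
#'
#' Emits a VCFv4.2 file with GT and DS fields reconstructed from the dosage
#' matrix (positions 1-based, as in the VCF convention).
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosage
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  for (i in seq_len(nrow(v))) {
    calls <- paste(gt[d[, i] + 1L], d[, i], sep = ":")
    writeLines(paste(c(v$chrom[i], v$pos[i], v$variant[i], v$ref[i], v$alt[i],
                       ".", "PASS", ".", "GT:DS", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a dosage matrix as TSV (variants in rows, donors in columns)
#' @param genotypes A `genotype_matrix`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$variants[, c("variant", "chrom", "pos", "ref", "alt", "maf")],
              as.data.frame(t(genotypes$dosage)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#' @param path File path.
#' @return A `genotype_matrix` (without principal components, which are
#'   recomputed).
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- c("variant", "chrom", "pos", "ref", "alt", "maf")
  dosage <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dosage) <- df$variant
  storage.mode(dosage) <- "integer"
  poly <- apply(dosage, 2, stats::var) > 0
  npc <- min(5L, nrow(dosage) - 1L)
  sc <- scale(dosage[, poly, drop = FALSE])
  pcs <- svd(sc, nu = npc, nv = 0)$u * sqrt(nrow(dosage) - 1)
  rownames(pcs) <- rownames(dosage)
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  v <- df[, meta_cols]
  v$gene <- sub("_v[0-9]+$", "", v$variant)
  structure(list(dosage = dosage, variants = v,
                 donors = data.frame(donor = rownames(dosage), pop = NA_integer_),
                 pcs = pcs),
            class = "genotype_matrix")
}

#' Write a nucleus table as MatrixMarket counts plus TSV metadata
#'
#' Produces `matrix.mtx` (genes x nuclei), `features.tsv`, `barcodes.tsv`
#' and `metadata.tsv` under `dir`.
#'
#' @param nuclei A `nucleus_table`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_nucleus_table <- function(nuclei, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(nuclei$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(nuclei$genes, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(nuclei$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(nuclei$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a nucleus table written by [write_nucleus_table()]
#' @param dir Directory containing matrix.mtx, features.tsv, barcodes.tsv,
#'   metadata.tsv.
#' @return A `nucleus_table`.
#' @export
read_nucleus_table <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  rownames(counts) <- genes$gene
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta, genes = genes),
            class = "nucleus_table")
}

#' Read GWAS summary statistics from TSV
#'
#' Expects columns variant, chrom, pos, ref, alt and either beta/se or p/n
#' (in the latter case |beta|/se is reconstructed from the p-value z-score
#' with unit-variance scaling; the sign is taken from a `beta` column when
#' present).
#'
#' @param path File path.
#' @return A `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (is.null(df$se) && !is.null(df$p) && !is.null(df$n)) {
    z <- qnorm(pmax(df$p / 2, 1e-300), lower.tail = FALSE)
    sgn <- if (!is.null(df$beta)) sign(df$beta) else 1
    df$se <- 1 / sqrt(df$n)
    df$beta <- sgn * z * df$se
  }
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Write the ground truth as JSON
#' @param truth A `ground_truth`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(genes = truth$genes[, setdiff(names(truth$genes), "active")],
              active = truth$genes$active,
              chains = truth$chains, cell_types = truth$cell_types)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
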