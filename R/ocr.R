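#' Density of functional elements in bins around lead variants
#'
#' Centers a window (default 2 Mb) at each lead variant, divides it into
#' fixed-width bins (default 10 kb), counts the functional elements (e.g.
#' open-chromatin regions) overlapping each bin, and sums the profiles over
#' all lead variants. Any overlap counts: an element straddling two bins is
#' counted in both.
#'
#' @param leads `data.frame` with `chrom` and `pos` columns (1-based variant
#'   positions), e.g. from [lead_variants()].
#' @param ocr Functional elements: a `GRanges`, a `data.frame` with
#'   `chrom`/`start`/`end` in BED convention (0-based half-open), or a path
#'   to a BED file.
#' @param window_bp Total window width centered at each variant.
#' @param bin_bp Bin width; `window_bp` must be a multiple.
#' @return `data.frame` of class `bin_density`: bin index, offset of the bin
#'   start relative to the variant, and summed element count.
#' @export
ocr_bin_density <- function(leads, ocr, window_bp = 2e6, bin_bp = 1e4) {
  nbin <- window_bp / bin_bp
  if (nbin != round(nbin)) stop("window_bp must be a multiple of bin_bp", call. = FALSE)
  gr <- as_granges_bed(ocr)
  offs <- (seq_len(nbin) - 1) * bin_bp - window_bp / 2
  counts <- numeric(nbin)
  for (i in seq_len(nrow(leads))) {
    starts <- leads$pos[i] + offs           # 0-based bin starts
    bins <- GenomicRanges::GRanges(
      leads$chrom[i],
      IRanges::IRanges(start = pmax(starts + 1, 1), end = starts + bin_bp)
    )
    counts <- counts + GenomicRanges::countOverlaps(bins, gr)
  }
  out <- data.frame(bin = seq_len(nbin), offset = offs, count = counts)
  class(out) <- c("bin_density", "data.frame")
  out
}

# Coerce BED-style input (0-based half-open) to GRanges (1-based closed).
as_granges_bed <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1) {
    lines <- readLines(x)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) < 3)) stop("malformed BED line", call. = FALSE)
    x <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start = as.numeric(vapply(parts, `[`, "", 2)),
                    end = as.numeric(vapply(parts, `[`, "", 3)),
                    stringsAsFactors = FALSE)
    if (any(is.na(x$start)) || any(is.na(x$end)) || any(x$end < x$start))
      stop("malformed BED line", call. = FALSE)
  }
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(start = x$start + 1, end = x$end))
}
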