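# Normalization: median-of-ratios size factors and TPM/FPKM.

#' Median-of-ratios size factors
#'
#' The classical count normalization: per sample, the median over eligible
#' genes of the ratio of the gene's count to its across-sample geometric
#' mean. Eligible genes are those with strictly positive counts in every
#' sample; the number of excluded genes is attached as attribute
#' \code{nExcluded}.
#'
#' @param counts integer matrix (genes x samples) or an
#'   [ExpressionStudy-class].
#' @return Named numeric vector of positive per-sample size factors.
#' @examples
#' m <- cbind(s1 = c(2, 2), s2 = c(8, 8))
#' rownames(m) <- c("g1", "g2")
#' sizeFactorsMedianOfRatios(m)  # 0.5, 2
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  if (is(counts, "ExpressionStudy")) counts <- assay(counts, "counts")
  counts <- as.matrix(counts)
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (!any(eligible))
    stopf("size factor estimation failed: no gene has positive counts in all samples")
  lc <- log(counts[eligible, , drop = FALSE])
  logGeo <- rowMeans(lc)
  sf <- exp(apply(lc - logGeo, 2, median))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stopf("size factor estimation produced a non-positive factor")
  structure(setNames(sf, colnames(counts)), nExcluded = sum(!eligible))
}

#' TPM and FPKM tables from counts and gene lengths
#'
#' \code{FPKM = count * 1e9 / (length * libsize)};
#' \code{TPM = rate * 1e6 / sum(rate)} with \code{rate = count / length}.
#' TPM columns sum to 1e6 by construction.
#'
#' @param counts matrix (genes x samples) or an [ExpressionStudy-class] with
#'   gene lengths in \code{rowData()}.
#' @param lengths per-gene lengths in bp (taken from the study if omitted).
#' @return List with matrices \code{tpm} and \code{fpkm}.
#' @export
computeTpmFpkm <- function(counts, lengths = NULL) {
  if (is(counts, "ExpressionStudy")) {
    if (is.null(lengths)) lengths <- geneLengths(counts)
    counts <- assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(lengths)) stopf("gene lengths are required")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || any(!is.finite(lengths)) ||
      any(lengths <= 0))
    stopf("gene lengths must be positive and cover every gene")
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("zero library size in sample '%s'",
                           colnames(counts)[which(lib == 0)[1]])
  fpkm <- sweep(counts / lengths * 1e9, 2, lib, "/")
  rate <- counts / lengths
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  list(tpm = tpm, fpkm = fpkm)
}
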