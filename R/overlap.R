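# Gene-set overlap enrichment: exact hypergeometric inference with BH
# correction, plus interval-overlap counting for region sets.

#' One-sided hypergeometric (Fisher exact) overlap test
#'
#' Enrichment p-value \code{P(X >= overlapN)} with
#' \code{X ~ Hypergeometric(universeN, aN, bN)}, evaluated through the
#' stable log-space tail of the hypergeometric distribution. The odds ratio
#' is the sample estimate from the 2x2 table, with a 0.5 continuity
#' correction applied to all cells when any cell is zero. A two-sided
#' alternative is available.
#'
#' @param universeN universe size.
#' @param aN,bN sizes of the two sets.
#' @param overlapN observed overlap (\code{<= min(aN, bN)}); may be a
#'   vector, in which case one row is returned per value.
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return data.frame with one row per overlap value: n_universe, n_a,
#'   n_b, n_overlap, odds_ratio, p.
#' @examples
#' hypergeometricOverlapTest(10, 5, 5, 5)$p  # 1/choose(10, 5)
#' @export
hypergeometricOverlapTest <- function(universeN, aN, bN, overlapN,
                                      alternative = c("greater",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  if (!isCount(universeN) || aN < 0 || bN < 0 || any(overlapN < 0))
    stopf("counts must be non-negative; universe must be positive")
  if (aN > universeN || bN > universeN)
    stopf("set sizes cannot exceed the universe size")
  if (any(overlapN > min(aN, bN)))
    stopf("overlap (%d) cannot exceed min(|A|, |B|) = %d",
          max(overlapN), min(aN, bN))
  if (any(overlapN < aN + bN - universeN))
    stopf("overlap (%d) below the minimum possible (%d) for these margins",
          min(overlapN), aN + bN - universeN)
  p <- if (alternative == "greater") {
    phyper(overlapN - 1, aN, universeN - aN, bN, lower.tail = FALSE)
  } else {
    vapply(overlapN, function(k)
      fisher.test(matrix(c(k, aN - k, bN - k,
                           universeN - aN - bN + k), 2))$p.value,
      numeric(1))
  }
  c11 <- overlapN; c12 <- aN - overlapN; c21 <- bN - overlapN
  c22 <- universeN - aN - bN + overlapN
  zero <- c11 == 0 | c12 == 0 | c21 == 0 | c22 == 0
  adj <- ifelse(zero, 0.5, 0)
  or <- ((c11 + adj) * (c22 + adj)) / ((c12 + adj) * (c21 + adj))
  data.frame(n_universe = universeN, n_a = aN, n_b = bN,
             n_overlap = overlapN, odds_ratio = or, p = p)
}

#' All-pairs overlap tests over a gene set collection
#'
#' Tests every row-set against every column-set on the collection's shared
#' universe; FDR is BH-adjusted across all cells of the matrix and a cell is
#' flagged significant at fdr < \code{alpha}.
#'
#' @param collection a [GeneSetCollection-class].
#' @param rows,cols set names (default: all sets for both).
#' @param alternative passed to [hypergeometricOverlapTest()].
#' @param alpha significance threshold on the adjusted values.
#' @return data.frame, one row per (row-set, col-set) cell: set_a, set_b,
#'   counts, odds_ratio, p, fdr, significant.
#' @export
overlapMatrix <- function(collection, rows = names(geneSets(collection)),
                          cols = names(geneSets(collection)),
                          alternative = "greater", alpha = 0.05) {
  sets <- geneSets(collection)
  unknown <- setdiff(c(rows, cols), names(sets))
  if (length(unknown))
    stopf("unknown set name(s): %s", paste(unknown, collapse = ", "))
  N <- length(geneUniverse(collection))
  grid <- expand.grid(set_a = rows, set_b = cols,
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    a <- sets[[grid$set_a[i]]]
    b <- sets[[grid$set_b[i]]]
    res <- hypergeometricOverlapTest(N, length(a), length(b),
                                     length(intersect(a, b)),
                                     alternative = alternative)
    cbind(grid[i, , drop = FALSE], res, row.names = NULL)
  })
  out <- do.call(rbind, cells)
  out$fdr <- bhAdjust(out$p)
  out$significant <- out$fdr < alpha
  out
}

#' Count and ratio of query regions overlapping a subject region set
#'
#' Reports how many query intervals overlap (>= 1 bp) any subject interval,
#' and the ratio of that count to the total number of queries -- the
#' region-overlap summary used for element-versus-peak comparisons, where a
#' ratio rather than a test is the reported quantity.
#'
#' @param query,subject GRanges.
#' @return List: n_total, n_overlap, ratio.
#' @export
regionOverlapRatio <- function(query, subject) {
  n <- sum(countOverlaps(query, subject, ignore.strand = TRUE) > 0)
  list(n_total = length(query), n_overlap = n,
       ratio = if (length(query)) n / length(query) else NA_real_)
}
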