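# Cluster label transfer by reference composition and per-cluster
# cross-species differential expression on integrated single-cell data.
# Cluster assignments and integration are consumed as input.

#' Transfer cell-type labels to clusters by reference composition
#'
#' Each cluster is annotated as the reference cell type with the largest
#' percentage among the cluster's reference-species cells. Clusters with no
#' reference cells are labeled "unassigned". Exact ties go to the
#' lexicographically smaller label and are flagged.
#'
#' @param cellMeta data.frame with columns cell_id, species, cluster and
#'   reference_label (NA outside the reference species).
#' @param referenceSpecies species whose labels are transferred.
#' @return data.frame: cluster, label, top_fraction, tie.
#' @export
transferClusterLabels <- function(cellMeta, referenceSpecies = "primateB") {
  clusters <- sort(unique(cellMeta$cluster))
  rows <- lapply(clusters, function(cl) {
    ref <- cellMeta[cellMeta$cluster == cl &
                      cellMeta$species == referenceSpecies, ]
    labs <- ref$reference_label[!is.na(ref$reference_label)]
    if (!length(labs))
      return(data.frame(cluster = cl, label = "unassigned",
                        top_fraction = NA_real_, tie = FALSE))
    frac <- table(labs) / length(labs)
    top <- max(frac)
    winners <- sort(names(frac)[frac == top])
    data.frame(cluster = cl, label = winners[1],
               top_fraction = unname(top), tie = length(winners) > 1)
  })
  do.call(rbind, rows)
}

#' Per-cluster cross-species differential expression (Wilcoxon)
#'
#' Within each cluster containing at least \code{minCells} cells of both
#' species, every gene is tested with a two-sided Wilcoxon rank-sum test
#' between the two species' cells; p-values are adjusted across genes
#' within each cluster (Bonferroni by default, BH selectable). Direction is
#' the sign of the mean difference (speciesA minus speciesB) and log2fc uses
#' pseudocount 1 on the group means. Genes constant across both groups get
#' p = 1. Clusters below the cell floor are skipped with a warning.
#'
#' @param expr genes x cells numeric matrix (column names = cell ids).
#' @param cellMeta data.frame with cell_id, species, cluster.
#' @param speciesA,speciesB species to compare.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param adjust "bonferroni" or "BH".
#' @param minCells minimum cells per species per cluster (default 3).
#' @return DataFrame: cluster, gene, log2fc, p, p_adj, direction,
#'   significant (p_adj < alpha).
#' @export
perClusterSpeciesDeg <- function(expr, cellMeta, speciesA, speciesB,
                                 alpha = 0.05,
                                 adjust = c("bonferroni", "BH"),
                                 minCells = 3) {
  adjust <- match.arg(adjust)
  cellMeta <- cellMeta[match(colnames(expr), cellMeta$cell_id), ]
  res <- list()
  for (cl in sort(unique(cellMeta$cluster))) {
    inCl <- cellMeta$cluster == cl
    ia <- which(inCl & cellMeta$species == speciesA)
    ib <- which(inCl & cellMeta$species == speciesB)
    if (length(ia) < minCells || length(ib) < minCells) {
      warnf("cluster '%s' skipped: fewer than %d cells in a species",
            cl, minCells)
      next
    }
    a <- expr[, ia, drop = FALSE]
    b <- expr[, ib, drop = FALSE]
    p <- vapply(seq_len(nrow(expr)), function(g) {
      xa <- a[g, ]; xb <- b[g, ]
      if (length(unique(c(xa, xb))) == 1) return(1)
      suppressWarnings(wilcox.test(xa, xb,
                                   alternative = "two.sided")$p.value)
    }, numeric(1))
    ma <- rowMeans(a); mb <- rowMeans(b)
    lfc <- log2(ma + 1) - log2(mb + 1)
    padj <- p.adjust(p, method = if (adjust == "BH") "BH" else "bonferroni")
    res[[length(res) + 1]] <- DataFrame(
      cluster = cl, gene = rownames(expr),
      log2fc = lfc, p = p, p_adj = padj,
      direction = ifelse(ma >= mb, "up_in_a", "down_in_a"),
      significant = padj < alpha)
  }
  if (!length(res))
    return(DataFrame(cluster = character(), gene = character(),
                     log2fc = numeric(), p = numeric(), p_adj = numeric(),
                     direction = character(), significant = logical()))
  do.call(rbind, res)
}

#' Fraction of DEGs linked to regulatory-element classes
#'
#' For each element class, the fraction of the DEG set linked to at least
#' one element of that class: \code{|DEGs n linked(class)| / |DEGs|}.
#'
#' @param degs character vector of DEG ids.
#' @param linkedGenesByClass named list of gene sets, one per element class.
#' @return data.frame: class, n_degs, n_linked, fraction (NA when the DEG
#'   set is empty).
#' @export
regulatoryFraction <- function(degs, linkedGenesByClass) {
  degs <- unique(degs)
  rows <- lapply(names(linkedGenesByClass), function(cl) {
    nl <- length(intersect(degs, linkedGenesByClass[[cl]]))
    data.frame(class = cl, n_degs = length(degs), n_linked = nl,
               fraction = if (length(degs)) nl / length(degs) else NA_real_)
  })
  do.call(rbind, rows)
}
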