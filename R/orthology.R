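# Cross-species gene anchoring, promoter windows and element-to-gene linkage.

#' Strand-aware promoter windows around transcription start sites
#'
#' For a + strand gene with TSS t the window covers \code{upstream} bp to the
#' genomic left and \code{downstream} bp to the right of (and including) the
#' TSS base; minus-strand windows are the mirror image. Windows are clipped
#' at the chromosome start. Defaults follow the common promoter definition of
#' 2 kb upstream and 1 kb downstream of the TSS.
#'
#' @param genes GRanges named by gene id, strand mandatory.
#' @param upstream,downstream window extent in bp.
#' @return GRanges of promoter windows named by gene id.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 15000), "+")
#' names(g) <- "geneA"
#' promoterWindows(g)  # chr1:8001-11000
#' @export
promoterWindows <- function(genes, upstream = 2000, downstream = 1000) {
  if (any(as.character(strand(genes)) == "*"))
    stopf("promoter windows require stranded genes")
  p <- suppressWarnings(promoters(genes, upstream = upstream,
                                  downstream = downstream))
  start(p) <- pmax(start(p), 1L)
  p
}

#' Link regulatory elements to genes within a distance window
#'
#' Distance is edge-to-edge between the element and the gene body (0 when
#' overlapping). \code{mode = "nearest"} keeps at most one gene per element
#' (minimum distance within \code{windowBp}; ties broken by the
#' lexicographically smaller gene id); \code{mode = "all_within"} keeps every
#' gene within the window. The default 500 kb window matches the convention
#' for assigning conserved noncoding elements to surrounding genes.
#'
#' @param elements GRanges of elements (names used as element ids).
#' @param genes GRanges of gene bodies named by gene id.
#' @param windowBp maximum distance in bp (inclusive).
#' @param mode "nearest" or "all_within".
#' @param useTss if TRUE measure distance to the TSS instead of the gene body.
#' @return DataFrame with columns element_id, gene_id, distance, mode.
#' @export
linkElementsToGenes <- function(elements, genes, windowBp = 5e5,
                                mode = c("nearest", "all_within"),
                                useTss = FALSE) {
  mode <- match.arg(mode)
  if (is.null(names(elements)))
    names(elements) <- sprintf("element_%d", seq_along(elements))
  if (is.null(names(genes))) stopf("genes must be named by gene id")
  target <- if (useTss)
    suppressWarnings(promoters(genes, upstream = 0, downstream = 1))
  else genes
  hits <- findOverlaps(elements, target, maxgap = windowBp,
                       ignore.strand = TRUE)
  if (!length(hits))
    return(DataFrame(element_id = character(), gene_id = character(),
                     distance = integer(), mode = character()))
  d <- distance(elements[queryHits(hits)], target[subjectHits(hits)],
                ignore.strand = TRUE)
  keep <- d <= windowBp
  df <- DataFrame(element_id = names(elements)[queryHits(hits)][keep],
                  gene_id = names(genes)[subjectHits(hits)][keep],
                  distance = as.integer(d[keep]), mode = mode)
  if (mode == "nearest" && nrow(df)) {
    ord <- order(df$element_id, df$distance, df$gene_id)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$element_id), , drop = FALSE]
  }
  df[order(match(df$element_id, names(elements)), df$gene_id), , drop = FALSE]
}

#' Project a gene set across species through a one-to-one ortholog table
#'
#' Ids without an ortholog row are dropped; the number dropped is reported
#' via a message and returned alongside the translated ids.
#'
#' @param orthologs data.frame with one column per species (see
#'   [readOrthologs()]).
#' @param geneSet character vector of ids in the \code{from} species.
#' @param from,to species column names.
#' @return List with \code{translated} (character) and \code{dropped}
#'   (integer count of ids without an ortholog row).
#' @export
projectGeneSets <- function(orthologs, geneSet, from, to) {
  if (!all(c(from, to) %in% colnames(orthologs)))
    stopf("species '%s' and '%s' must be columns of the ortholog table",
          from, to)
  idx <- match(geneSet, orthologs[[from]])
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(dropped, " gene(s) dropped: no one-to-one ortholog from '",
            from, "' to '", to, "'")
  list(translated = orthologs[[to]][idx[!is.na(idx)]],
       dropped = dropped)
}
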