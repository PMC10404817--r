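#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowData assayNames
NULL

#' ExpressionStudy: a per-species gene-by-sample count table with metadata
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' carrying a single integer \code{counts} assay. Column data must declare at
#' least \code{species}, \code{tissue} and \code{group} (\code{"brain"} or
#' \code{"nonbrain"}); QC columns \code{uniquely_mapped_reads} and
#' \code{unique_map_rate} and covariates \code{age}, \code{sex}, \code{rin}
#' are carried when available. Per-gene lengths (bp) live in
#' \code{rowData()$gene_length} and feed TPM/FPKM computation.
#'
#' @seealso [expressionStudy()], [readCounts()], [simulateExpressionStudy()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be finite non-negative integers")
  }
  cd <- colData(object)
  need <- c("species", "tissue", "group")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing sample metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if ("group" %in% colnames(cd) &&
      !all(cd$group %in% c("brain", "nonbrain")))
    msg <- c(msg, "group must be 'brain' or 'nonbrain'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param sampleMeta data.frame of per-sample records; must contain
#'   \code{sample_id} matching \code{colnames(counts)} (any order), plus
#'   \code{species}, \code{tissue}, \code{group}.
#' @param geneLengths optional named numeric vector of gene lengths (bp).
#' @return An [ExpressionStudy-class] object.
#' @examples
#' cts <- matrix(0:3, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), species = "hsa",
#'                    tissue = c("brain", "liver"),
#'                    group = c("brain", "nonbrain"))
#' expressionStudy(cts, meta)
#' @export
expressionStudy <- function(counts, sampleMeta, geneLengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stopf("counts must carry gene rownames and sample colnames")
  if (!"sample_id" %in% colnames(sampleMeta))
    stopf("sample metadata must contain a 'sample_id' column")
  if (!setequal(sampleMeta$sample_id, colnames(counts)))
    stopf("sample ids of counts and metadata disagree: %s",
          paste(union(setdiff(colnames(counts), sampleMeta$sample_id),
                      setdiff(sampleMeta$sample_id, colnames(counts))),
                collapse = ", "))
  sampleMeta <- sampleMeta[match(colnames(counts), sampleMeta$sample_id), ,
                           drop = FALSE]
  rownames(sampleMeta) <- sampleMeta$sample_id
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(geneLengths)) {
    if (is.null(names(geneLengths)))
      names(geneLengths) <- rownames(counts)
    rd$gene_length <- unname(geneLengths[rownames(counts)])
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(sampleMeta),
                             rowData = rd)
  new("ExpressionStudy", se)
}

#' Gene lengths of an ExpressionStudy
#' @param study an [ExpressionStudy-class].
#' @return Named numeric vector of gene lengths, or NULL if absent.
#' @export
geneLengths <- function(study) {
  rd <- rowData(study)
  if (!"gene_length" %in% colnames(rd)) return(NULL)
  setNames(rd$gene_length, rownames(study))
}

#' BlockCoordinateMap: piecewise mapping between two assemblies
#'
#' A set of equal-width source/target block pairs; coordinates between blocks
#' are unmappable. Orientation \code{"-"} reverses coordinates within the
#' block. This is the minimal contract needed for liftOver-style interval
#' conversion; the on-disk dialect is a 7-column TSV (see [readBlockMap()]).
#'
#' @slot src GRanges of source blocks (non-overlapping).
#' @slot tgt GRanges of target blocks, same widths as \code{src}.
#' @slot orientation character vector of "+" or "-" per block.
#' @seealso [mapIntervals()], [invertBlockMap()]
#' @export
setClass("BlockCoordinateMap",
         representation(src = "GRanges", tgt = "GRanges",
                        orientation = "character"))

setValidity("BlockCoordinateMap", function(object) {
  msg <- character()
  n <- length(object@src)
  if (length(object@tgt) != n || length(object@orientation) != n)
    msg <- c(msg, "src, tgt and orientation must have equal length")
  else {
    if (any(width(object@src) != width(object@tgt)))
      msg <- c(msg, "source and target block widths must match")
    if (!all(object@orientation %in% c("+", "-")))
      msg <- c(msg, "orientation must be '+' or '-'")
    if (n > 1 && sum(width(reduce(object@src, min.gapwidth = 0L))) <
        sum(width(object@src)))
      msg <- c(msg, "source blocks must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BlockCoordinateMap
#' @param src,tgt GRanges of source and target blocks (parallel, equal widths).
#' @param orientation character vector "+"/"-" per block (default all "+").
#' @return A [BlockCoordinateMap-class].
#' @export
blockCoordinateMap <- function(src, tgt, orientation = rep("+", length(src))) {
  new("BlockCoordinateMap", src = granges(src), tgt = granges(tgt),
      orientation = as.character(orientation))
}

#' @describeIn blockCoordinateMap source blocks
#' @param map a [BlockCoordinateMap-class].
#' @export
sourceBlocks <- function(map) map@src

#' @describeIn blockCoordinateMap target blocks
#' @export
targetBlocks <- function(map) map@tgt

#' @describeIn blockCoordinateMap per-block orientation
#' @export
blockOrientation <- function(map) map@orientation

setMethod("show", "BlockCoordinateMap", function(object) {
  cat("BlockCoordinateMap with", length(object@src), "block(s);",
      sum(width(object@src)), "bp mapped\n")
})

#' GeneSetCollection: named gene sets over an explicit universe
#'
#' The universe is always explicit (never inferred from set unions); every
#' set must be a subset of it. Used for hypergeometric overlap testing.
#'
#' @slot universe character vector of gene ids (unique).
#' @slot sets named list of character vectors, each a subset of the universe.
#' @seealso [geneSetCollection()], [overlapMatrix()]
#' @export
setClass("GeneSetCollection",
         representation(universe = "character", sets = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe ids must be unique")
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "sets must be uniquely named")
    bad <- vapply(object@sets,
                  function(s) length(setdiff(s, object@universe)) > 0,
                  logical(1))
    if (any(bad))
      msg <- c(msg, paste0("set(s) not contained in universe: ",
                           paste(names(object@sets)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param universe character vector of gene ids.
#' @param sets named list of character vectors (subsets of the universe).
#' @return A [GeneSetCollection-class].
#' @examples
#' geneSetCollection(letters, list(vowels = c("a", "e", "i")))
#' @export
geneSetCollection <- function(universe, sets = list()) {
  new("GeneSetCollection", universe = as.character(universe),
      sets = lapply(sets, function(s) unique(as.character(s))))
}

#' @describeIn geneSetCollection the declared universe
#' @param x a [GeneSetCollection-class].
#' @export
geneUniverse <- function(x) x@universe

#' @describeIn geneSetCollection the named sets
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@universe), "universe genes,",
      length(object@sets), "set(s)\n")
  if (length(object@sets))
    cat(paste0("  ", names(object@sets), " (",
               lengths(object@sets), ")", collapse = "\n"), "\n")
})

#' PSBEGReport: output of the brain-biased gene decision tree
#'
#' Holds the candidate set after the cross-species set logic, the final set
#' after the organ-top filters, the experimental subset from the alternative
#' (brain-lowly-expressed) branch, and a per-gene audit trail assigning every
#' universe gene exactly one terminal disposition.
#'
#' @slot candidateSet character, genes surviving the set logic.
#' @slot finalSet character, genes surviving all organ filters (main branch).
#' @slot experimentalSubset character, genes from the alternative branch.
#' @slot audit DFrame with columns \code{gene} and \code{disposition}.
#' @seealso [runPsbegPipeline()]
#' @export
setClass("PSBEGReport",
         representation(candidateSet = "character", finalSet = "character",
                        experimentalSubset = "character", audit = "DFrame"))

setValidity("PSBEGReport", function(object) {
  msg <- character()
  if (!all(c("gene", "disposition") %in% colnames(object@audit)))
    msg <- c(msg, "audit must have 'gene' and 'disposition' columns")
  if (!all(object@finalSet %in% object@candidateSet))
    msg <- c(msg, "finalSet must be contained in candidateSet")
  if (anyDuplicated(object@audit$gene))
    msg <- c(msg, "audit must list each gene exactly once")
  if (length(msg)) msg else TRUE
})

#' @describeIn PSBEGReport-class genes surviving the set logic
#' @param report a [PSBEGReport-class].
#' @export
candidateSet <- function(report) report@candidateSet

#' @describeIn PSBEGReport-class genes surviving all filters
#' @export
finalSet <- function(report) report@finalSet

#' @describeIn PSBEGReport-class alternative-branch genes
#' @export
experimentalSubset <- function(report) report@experimentalSubset

#' @describeIn PSBEGReport-class per-gene audit trail
#' @export
auditTrail <- function(report) report@audit

setMethod("show", "PSBEGReport", function(object) {
  cat("PSBEGReport:", length(object@candidateSet), "candidate(s) ->",
      length(object@finalSet), "final gene(s);",
      length(object@experimentalSubset), "in experimental subset\n")
})

#' DEResult: per-gene differential expression calls
#'
#' A \link[S4Vectors]{DataFrame} extension with columns \code{log2fc},
#' \code{p}, \code{fdr} and \code{call} (one of \code{up_in_brain},
#' \code{down_in_brain}, \code{ns}); the thresholds used are stored in
#' \code{metadata()} as \code{q} and \code{lfcMin}. A gene is called iff
#' \code{fdr < q} and \code{|log2fc| >= lfcMin}.
#'
#' @seealso [brainVsNonbrainDE()]
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
  msg <- character()
  need <- c("log2fc", "p", "fdr", "call")
  if (!all(need %in% colnames(object)))
    msg <- c(msg, paste0("missing column(s): ",
                         paste(setdiff(need, colnames(object)), collapse = ", ")))
  else {
    if (!all(object$call %in% c("up_in_brain", "down_in_brain", "ns")))
      msg <- c(msg, "call must be up_in_brain/down_in_brain/ns")
    q <- metadata(object)$q; lfc <- metadata(object)$lfcMin
    if (!is.null(q) && !is.null(lfc)) {
      ok <- is.finite(object$fdr) & is.finite(object$log2fc)
      shouldCall <- ok & object$fdr < q & abs(object$log2fc) >= lfc
      if (!all((object$call != "ns") == shouldCall))
        msg <- c(msg, "call is inconsistent with fdr/log2fc thresholds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Genes called differentially expressed in a given direction
#' @param de a [DEResult-class].
#' @param direction "up_in_brain", "down_in_brain" or "any".
#' @return Character vector of gene ids.
#' @export
deGenes <- function(de, direction = c("up_in_brain", "down_in_brain", "any")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") de$call != "ns" else de$call == direction
  rownames(de)[keep]
}
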