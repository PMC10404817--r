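# Decision-tree selection of primate-specific brain-biased genes (PSBEGs)
# and the fetal-zone expression filter.

#' Cross-species candidate set logic
#'
#' Candidates are the brain-highly-expressed genes shared by the two primates
#' minus those also brain-high in the nonprimate, plus the genes brain-high
#' in the reference primate only:
#' \code{((H \%in\% M) \\ T) U (H \\ (M U T))}.
#'
#' @param hUp,mUp,tUp brain-highly-expressed gene sets of the reference
#'   primate, comparator primate and nonprimate, all on the shared ortholog
#'   universe.
#' @param universe the ortholog universe; ids outside it are an error.
#' @return Sorted character vector of candidate gene ids.
#' @examples
#' candidateSetLogic(c("a", "b", "c"), c("b", "c", "d"), "c",
#'                   universe = letters[1:4])  # "a" "b"
#' @export
candidateSetLogic <- function(hUp, mUp, tUp, universe) {
  out <- setdiff(unique(c(hUp, mUp, tUp)), universe)
  if (length(out))
    stopf("gene id(s) outside the ortholog universe: %s",
          paste(utils::head(out, 3), collapse = ", "))
  sort(union(setdiff(intersect(hUp, mUp), tUp),
             setdiff(hUp, union(mUp, tUp))))
}

#' Per-organ expression summary
#'
#' Summarizes median-of-ratios-normalized counts per gene per organ (tissue),
#' the substrate for the organ-top filters. The summary statistic defaults to
#' the median (robust); the mean is available.
#'
#' @param study an [ExpressionStudy-class].
#' @param sizeFactors optional precomputed size factors.
#' @param stat "median" or "mean".
#' @return List with \code{values} (gene x organ matrix), \code{brainOrgan}
#'   (named logical: is the organ a brain organ, from the metadata
#'   \code{group} column) and \code{stat}.
#' @export
organSummary <- function(study, sizeFactors = NULL,
                         stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianOfRatios(study)
  norm <- sweep(assay(study, "counts"), 2,
                sizeFactors[colnames(study)], "/")
  cd <- colData(study)
  organs <- unique(as.character(cd$tissue))
  fun <- if (stat == "median") median else mean
  vals <- vapply(organs, function(o) {
    apply(norm[, cd$tissue == o, drop = FALSE], 1, fun)
  }, numeric(nrow(norm)))
  brainOrgan <- vapply(organs, function(o) {
    g <- unique(cd$group[cd$tissue == o])
    if (length(g) != 1)
      stopf("organ '%s' maps to both brain and nonbrain groups", o)
    g == "brain"
  }, logical(1))
  list(values = vals, brainOrgan = brainOrgan, stat = stat)
}

#' Keep genes whose top organ is (non)brain
#'
#' A gene survives \code{require = "brain_top"} iff its strict unique argmax
#' organ is a brain organ, and \code{"nonbrain_top"} iff it is a nonbrain
#' organ. Ties for the maximum fail the filter (a unique "highest" organ is
#' required). Genes absent from the summary are dropped with a warning.
#'
#' @param summary an organ summary as returned by [organSummary()].
#' @param require "brain_top" or "nonbrain_top".
#' @param genes gene ids to filter.
#' @return Character vector of surviving gene ids (order of \code{genes}).
#' @export
organTopFilter <- function(summary, require = c("brain_top", "nonbrain_top"),
                           genes) {
  require <- match.arg(require)
  vals <- summary$values
  missing <- setdiff(genes, rownames(vals))
  if (length(missing)) {
    warnf("organTopFilter: %d gene(s) absent from the organ summary, dropped",
          length(missing))
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) return(character(0))
  sub <- vals[genes, , drop = FALSE]
  keep <- vapply(seq_len(nrow(sub)), function(i) {
    v <- sub[i, ]
    top <- which(v == max(v))
    length(top) == 1 &&
      summary$brainOrgan[colnames(sub)[top]] == (require == "brain_top")
  }, logical(1))
  genes[keep]
}

#' Run the full PSBEG decision tree
#'
#' Step 1: [candidateSetLogic()] on the per-species brain-highly-expressed
#' sets (projected to the reference species' ids). Step 2: keep candidates
#' whose top organ in the reference primate is a brain organ. Step 3 (main
#' branch): keep genes whose top organ is nonbrain in the nonprimate, then
#' nonbrain in the outgroup; survivors are the final PSBEG set. Step 3
#' (alternative branch): step-2 survivors intersected with the nonprimate
#' brain-lowly-expressed set, then the outgroup nonbrain-top filter; the
#' result is the experimental subset. Every universe gene receives exactly
#' one terminal disposition in the audit trail.
#'
#' @param deResults named list of [DEResult-class] per species; names must
#'   include the four roles given in \code{roles}.
#' @param organSummaries named list of [organSummary()] outputs for the
#'   reference, nonprimate and outgroup species (keyed by role).
#' @param orthologs one-to-one ortholog table whose columns are the roles.
#' @param roles named character vector mapping
#'   \code{reference}, \code{comparator}, \code{nonprimate}, \code{outgroup}
#'   to species column names.
#' @return A [PSBEGReport-class] (gene ids in the reference species).
#' @export
runPsbegPipeline <- function(deResults, organSummaries, orthologs,
                             roles = c(reference = "primateA",
                                       comparator = "primateB",
                                       nonprimate = "nonprimate",
                                       outgroup = "outgroup")) {
  need <- c("reference", "comparator", "nonprimate", "outgroup")
  if (!all(need %in% names(roles)))
    stopf("roles must name reference, comparator, nonprimate and outgroup")
  ref <- roles[["reference"]]
  universe <- orthologs[[ref]]
  if (is.null(universe) || !length(universe))
    stopf("empty ortholog universe for reference species '%s'", ref)

  toRef <- function(ids, from) {
    if (from == ref) return(intersect(ids, universe))
    suppressMessages(projectGeneSets(orthologs, ids, from, ref)$translated)
  }
  fromRef <- function(ids, to) {
    if (to == ref) return(ids)
    suppressMessages(projectGeneSets(orthologs, ids, ref, to)$translated)
  }

  hUp <- toRef(deGenes(deResults[[roles[["reference"]]]], "up_in_brain"),
               ref)
  mUp <- toRef(deGenes(deResults[[roles[["comparator"]]]], "up_in_brain"),
               roles[["comparator"]])
  tUp <- toRef(deGenes(deResults[[roles[["nonprimate"]]]], "up_in_brain"),
               roles[["nonprimate"]])
  tDown <- toRef(deGenes(deResults[[roles[["nonprimate"]]]], "down_in_brain"),
                 roles[["nonprimate"]])

  candidates <- candidateSetLogic(hUp, mUp, tUp, universe)

  disposition <- setNames(rep("not_candidate", length(universe)), universe)
  disposition[candidates] <- "candidate"

  # step 2: reference primate brain-top filter
  step2 <- organTopFilter(organSummaries[[roles[["reference"]]]],
                          "brain_top", candidates)
  disposition[setdiff(candidates, step2)] <- "eliminated_reference_organ_filter"

  # step 3 main branch: nonprimate then outgroup nonbrain-top
  npIds <- fromRef(step2, roles[["nonprimate"]])
  npKeep <- organTopFilter(organSummaries[[roles[["nonprimate"]]]],
                           "nonbrain_top", npIds)
  step3a <- step2[npIds %in% npKeep]
  disposition[setdiff(step2, step3a)] <- "eliminated_nonprimate_organ_filter"

  ogIds <- fromRef(step3a, roles[["outgroup"]])
  ogKeep <- organTopFilter(organSummaries[[roles[["outgroup"]]]],
                           "nonbrain_top", ogIds)
  finalSet <- step3a[ogIds %in% ogKeep]
  disposition[setdiff(step3a, finalSet)] <- "eliminated_outgroup_organ_filter"
  disposition[finalSet] <- "psbeg"

  # alternative branch: step2 survivors in the nonprimate brain-low set,
  # then the outgroup filter
  alt <- intersect(step2, tDown)
  altOg <- fromRef(alt, roles[["outgroup"]])
  altKeep <- organTopFilter(organSummaries[[roles[["outgroup"]]]],
                            "nonbrain_top", altOg)
  experimental <- alt[altOg %in% altKeep]

  audit <- DataFrame(gene = universe,
                     disposition = unname(disposition[universe]),
                     experimental = universe %in% experimental)
  new("PSBEGReport", candidateSet = candidates, finalSet = finalSet,
      experimentalSubset = experimental, audit = audit)
}

#' Fetal-zone expression filter
#'
#' Keeps a gene iff strictly more than \code{fraction} of the human-like
#' fetal samples have \code{log2(FPKM + 1) > threshold} AND strictly more
#' than \code{fraction} of the mouse-like fetal samples have
#' \code{log2(FPKM + 1) < threshold}. A sample exactly at the threshold
#' counts against both criteria. Genes missing from either table are dropped
#' with a warning.
#'
#' @param fpkmHuman,fpkmMouse FPKM matrices (genes x fetal-zone samples).
#' @param genes gene ids to filter (shared id space across the two tables).
#' @param threshold log2(FPKM+1) cut point (default 1).
#' @param fraction strict sample-fraction bound (default 0.80).
#' @return Character vector of surviving gene ids.
#' @export
fetalZoneFilter <- function(fpkmHuman, fpkmMouse, genes,
                            threshold = 1.0, fraction = 0.80) {
  missing <- setdiff(genes, intersect(rownames(fpkmHuman),
                                      rownames(fpkmMouse)))
  if (length(missing)) {
    warnf("fetalZoneFilter: %d gene(s) missing from an FPKM table, dropped",
          length(missing))
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) return(character(0))
  lh <- log2(fpkmHuman[genes, , drop = FALSE] + 1)
  lm <- log2(fpkmMouse[genes, , drop = FALSE] + 1)
  keep <- rowMeans(lh > threshold) > fraction &
    rowMeans(lm < threshold) > fraction
  genes[keep]
}
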