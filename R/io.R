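# File readers and writers. On-disk interval formats (BED, BEDPE, block-map
# TSV) are 0-based half-open; everything is converted to GRanges (1-based
# closed) at this boundary and converted back on write. Readers validate
# strictly and report file, line and rule on failure.

readTsv <- function(path, what = "table") {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a counts table and sample metadata into an ExpressionStudy
#'
#' @param countsPath TSV with a header row of sample ids; first column gene
#'   ids. Entries must be non-negative integers.
#' @param metaPath companion TSV of per-sample records with a
#'   \code{sample_id} column.
#' @param geneLengthsPath optional two-column TSV (gene_id, length).
#' @return An [ExpressionStudy-class].
#' @seealso [writeCounts()]
#' @export
readCounts <- function(countsPath, metaPath, geneLengthsPath = NULL) {
  tab <- readTsv(countsPath, "counts")
  if (ncol(tab) < 2) stopf("%s: need a gene-id column plus samples", countsPath)
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stopf("%s: non-integer or negative count at gene '%s', sample '%s'",
          countsPath, genes[bad[1, 1]], colnames(mat)[bad[1, 2]])
  rownames(mat) <- genes
  storage.mode(mat) <- "integer"
  meta <- readTsv(metaPath, "metadata")
  if (!"sample_id" %in% colnames(meta))
    stopf("%s: metadata must contain a 'sample_id' column", metaPath)
  lens <- NULL
  if (!is.null(geneLengthsPath)) {
    lt <- readTsv(geneLengthsPath, "gene lengths")
    lens <- setNames(as.numeric(lt[[2]]), as.character(lt[[1]]))
  }
  expressionStudy(mat, meta, geneLengths = lens)
}

#' Write an ExpressionStudy as counts + metadata TSV
#' @param study an [ExpressionStudy-class].
#' @param countsPath,metaPath output TSV paths.
#' @param geneLengthsPath optional output path for gene lengths.
#' @export
writeCounts <- function(study, countsPath, metaPath, geneLengthsPath = NULL) {
  cts <- assay(study, "counts")
  out <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE)
  write.table(out, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(colData(study)), metaPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  lens <- geneLengths(study)
  if (!is.null(geneLengthsPath) && !is.null(lens))
    write.table(data.frame(gene_id = names(lens), length = lens),
                geneLengthsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

splitLines <- function(path, minFields, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < minFields)
  if (length(short))
    stopf("%s: line %d has fewer than %d tab-separated fields (%s)",
          path, short[1], minFields, what)
  fields
}

asCoord <- function(x, path, i, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(!is.finite(v)) || any(v != round(v)) || any(v < 0))
    stopf("%s: line %d: %s must be a non-negative integer", path, i[1], what)
  v
}

#' Read a BED file into a GRanges
#'
#' BED's 0-based half-open coordinates become 1-based closed in the returned
#' GRanges. Optional columns 4-6 populate \code{names()}, \code{score} and
#' strand; missing names are generated and names must be unique.
#'
#' @param path BED path (>= 3 tab-separated columns).
#' @return A GRanges.
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  fields <- splitLines(path, 3, "BED")
  if (!length(fields)) return(GRanges())
  chrom <- vapply(fields, `[`, "", 1)
  if (any(!nzchar(chrom))) stopf("%s: empty chrom field", path)
  s0 <- asCoord(vapply(fields, `[`, "", 2), path,
                seq_along(fields), "start")
  e0 <- asCoord(vapply(fields, `[`, "", 3), path,
                seq_along(fields), "end")
  bad <- which(s0 >= e0)
  if (length(bad))
    stopf("%s: line %d: start (%s) must be < end (%s)", path, bad[1],
          s0[bad[1]], e0[bad[1]])
  nm <- if (all(lengths(fields) >= 4)) vapply(fields, `[`, "", 4)
        else sprintf("feature_%d", seq_along(fields))
  if (anyDuplicated(nm))
    stopf("%s: duplicate interval name '%s'", path, nm[duplicated(nm)][1])
  score <- if (all(lengths(fields) >= 5))
    suppressWarnings(as.numeric(vapply(fields, `[`, "", 5))) else NULL
  strand <- if (all(lengths(fields) >= 6)) {
    st <- vapply(fields, `[`, "", 6)
    st[!st %in% c("+", "-")] <- "*"
    st
  } else "*"
  gr <- GRanges(chrom, IRanges(s0 + 1, e0), strand = strand)
  names(gr) <- nm
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

#' Write a GRanges as BED (6 columns)
#' @param gr a GRanges; names become the BED name column.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  nm <- if (is.null(names(gr))) sprintf("feature_%d", seq_along(gr))
        else names(gr)
  score <- if ("score" %in% colnames(mcols(gr))) mcols(gr)$score else 0
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  out <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                    nm, score, st)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a block coordinate map (7-column TSV)
#'
#' Dialect: \code{src_chrom, src_start, src_end, tgt_chrom, tgt_start,
#' tgt_end, orientation}, coordinates 0-based half-open, no header. Source
#' and target block lengths must agree and source blocks must not overlap.
#'
#' @param path TSV path. An empty file yields an empty map (every query
#'   unmappable).
#' @return A [BlockCoordinateMap-class].
#' @export
readBlockMap <- function(path) {
  if (!file.exists(path)) stopf("block map file not found: %s", path)
  fields <- splitLines(path, 7, "block map")
  if (!length(fields))
    return(blockCoordinateMap(GRanges(), GRanges(), character()))
  i <- seq_along(fields)
  ss <- asCoord(vapply(fields, `[`, "", 2), path, i, "src_start")
  se <- asCoord(vapply(fields, `[`, "", 3), path, i, "src_end")
  ts <- asCoord(vapply(fields, `[`, "", 5), path, i, "tgt_start")
  te <- asCoord(vapply(fields, `[`, "", 6), path, i, "tgt_end")
  ori <- vapply(fields, `[`, "", 7)
  bad <- which(ss >= se | ts >= te)
  if (length(bad))
    stopf("%s: line %d: block start must be < end", path, bad[1])
  bad <- which((se - ss) != (te - ts))
  if (length(bad))
    stopf("%s: line %d: source block length %d != target block length %d",
          path, bad[1], se[bad[1]] - ss[bad[1]], te[bad[1]] - ts[bad[1]])
  bad <- which(!ori %in% c("+", "-"))
  if (length(bad))
    stopf("%s: line %d: orientation must be '+' or '-'", path, bad[1])
  map <- blockCoordinateMap(
    GRanges(vapply(fields, `[`, "", 1), IRanges(ss + 1, se)),
    GRanges(vapply(fields, `[`, "", 4), IRanges(ts + 1, te)),
    ori)
  validObject(map)
  map
}

#' Write a BlockCoordinateMap in the 7-column TSV dialect
#' @param map a [BlockCoordinateMap-class].
#' @param path output path.
#' @export
writeBlockMap <- function(map, path) {
  src <- sourceBlocks(map); tgt <- targetBlocks(map)
  out <- data.frame(as.character(seqnames(src)), start(src) - 1L, end(src),
                    as.character(seqnames(tgt)), start(tgt) - 1L, end(tgt),
                    blockOrientation(map))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' @param path BEDPE path (>= 6 columns: chromA, startA, endA, chromB,
#'   startB, endB; optional name, score).
#' @return A \link[S4Vectors]{Pairs} of anchor GRanges, with loop names and
#'   optional scores in \code{mcols()}.
#' @export
readLoops <- function(path) {
  if (!file.exists(path)) stopf("BEDPE file not found: %s", path)
  fields <- splitLines(path, 6, "BEDPE")
  if (!length(fields))
    return(Pairs(GRanges(), GRanges()))
  i <- seq_along(fields)
  sA <- asCoord(vapply(fields, `[`, "", 2), path, i, "startA")
  eA <- asCoord(vapply(fields, `[`, "", 3), path, i, "endA")
  sB <- asCoord(vapply(fields, `[`, "", 5), path, i, "startB")
  eB <- asCoord(vapply(fields, `[`, "", 6), path, i, "endB")
  bad <- which(sA >= eA | sB >= eB)
  if (length(bad))
    stopf("%s: line %d: anchor start must be < end", path, bad[1])
  a1 <- GRanges(vapply(fields, `[`, "", 1), IRanges(sA + 1, eA))
  a2 <- GRanges(vapply(fields, `[`, "", 4), IRanges(sB + 1, eB))
  nm <- if (all(lengths(fields) >= 7)) vapply(fields, `[`, "", 7)
        else sprintf("loop_%d", i)
  p <- Pairs(a1, a2, names = nm)
  if (all(lengths(fields) >= 8))
    mcols(p)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[`, "", 8)))
  p
}

#' Write loops as BEDPE
#' @param loops a Pairs of anchor GRanges.
#' @param path output path.
#' @export
writeLoops <- function(loops, path) {
  a1 <- first(loops); a2 <- second(loops)
  nm <- if (is.null(names(loops))) sprintf("loop_%d", seq_along(loops))
        else names(loops)
  score <- if ("score" %in% colnames(mcols(loops))) mcols(loops)$score else 0
  out <- data.frame(as.character(seqnames(a1)), start(a1) - 1L, end(a1),
                    as.character(seqnames(a2)), start(a2) - 1L, end(a2),
                    nm, score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts either the package's 5-column TSV dialect (header
#' \code{gene_id, chrom, start, end, strand}; 0-based half-open) or GFF/GTF
#' (1-based inclusive; records with \code{type == "gene"} are used), both
#' converted to GRanges. Strand is mandatory for genes.
#'
#' @param path annotation path (.tsv/.txt, or .gtf/.gff/.gff3 via
#'   \pkg{rtracklayer}).
#' @return A GRanges named by gene id with strand set.
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stopf("gene annotation not found: %s", path)
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stopf("reading GFF/GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- as.character(gr$gene_id)
    gr <- granges(gr)
    names(gr) <- ids
  } else {
    tab <- readTsv(path, "gene annotation")
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% colnames(tab)))
      stopf("%s: gene annotation needs columns %s", path,
            paste(need, collapse = ", "))
    if (any(tab$start >= tab$end))
      stopf("%s: line %d: start must be < end", path,
            which(tab$start >= tab$end)[1])
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1, tab$end),
                  strand = tab$strand)
    names(gr) <- tab$gene_id
  }
  if (anyDuplicated(names(gr)))
    stopf("%s: duplicate gene_id '%s'", path, names(gr)[duplicated(names(gr))][1])
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stopf("%s: every gene must have strand '+' or '-'", path)
  gr
}

#' Write gene annotations in the 5-column TSV dialect
#' @param genes GRanges named by gene id.
#' @param path output path.
#' @export
writeGeneAnnotation <- function(genes, path) {
  out <- data.frame(gene_id = names(genes),
                    chrom = as.character(seqnames(genes)),
                    start = start(genes) - 1L, end = end(genes),
                    strand = as.character(strand(genes)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-to-one ortholog table
#'
#' TSV with one column per species (header = species names), one row per
#' ortholog group. No id may appear twice within its species column.
#'
#' @param path TSV path.
#' @return data.frame with one character column per species.
#' @export
readOrthologs <- function(path) {
  tab <- readTsv(path, "ortholog table")
  if (ncol(tab) < 2) stopf("%s: need at least two species columns", path)
  for (sp in colnames(tab)) {
    tab[[sp]] <- as.character(tab[[sp]])
    dup <- tab[[sp]][duplicated(tab[[sp]])]
    if (length(dup))
      stopf("%s: gene id '%s' appears twice in species column '%s'",
            path, dup[1], sp)
    if (anyNA(tab[[sp]]) || any(!nzchar(tab[[sp]])))
      stopf("%s: missing gene id in species column '%s'", path, sp)
  }
  tab
}

#' Write a one-to-one ortholog table
#' @param orthologs data.frame with one column per species.
#' @param path output path.
#' @export
writeOrthologs <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
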