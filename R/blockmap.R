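# Interval conversion through block coordinate maps (liftOver-style).

#' Map intervals to another assembly through a block coordinate map
#'
#' Bases are mapped block-wise. An interval is unmappable when the fraction
#' of its bases covered by map blocks falls below \code{minMappedFraction},
#' or when its mapped pieces land on different target chromosomes or mixed
#' orientations (split conversions count as failed). Otherwise the returned
#' range is the span of the mapped pieces. The default 0.95 minimum mapped
#' fraction mirrors common liftOver practice.
#'
#' @param x GRanges on the map's source assembly.
#' @param map a [BlockCoordinateMap-class].
#' @param minMappedFraction minimum fraction of bases that must map.
#' @return A GRangesList parallel to \code{x}; unmappable queries are
#'   empty elements, mapped queries hold a single range.
#' @examples
#' m <- blockCoordinateMap(
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)),
#'   GenomicRanges::GRanges("chrM", IRanges::IRanges(51, 150)))
#' mapIntervals(GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20)), m)
#' @export
mapIntervals <- function(x, map, minMappedFraction = 0.95) {
  src <- sourceBlocks(map); tgt <- targetBlocks(map)
  ori <- blockOrientation(map)
  n <- length(x)
  hits <- findOverlaps(x, src, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  okQ <- logical(n)
  resChr <- character(n); resS <- integer(n); resE <- integer(n)
  if (length(hits)) {
    piece <- pintersect(granges(x)[qh], src[sh], ignore.strand = TRUE)
    offS <- start(piece) - start(src)[sh]
    offE <- end(piece) - start(src)[sh]
    plus <- ori[sh] == "+"
    tS <- ifelse(plus, start(tgt)[sh] + offS, end(tgt)[sh] - offE)
    tE <- ifelse(plus, start(tgt)[sh] + offE, end(tgt)[sh] - offS)
    tChr <- as.character(seqnames(tgt))[sh]
    covered <- width(piece)
    f <- factor(qh, levels = seq_len(n))
    coveredBp <- vapply(split(covered, f), sum, numeric(1))
    oneChr <- vapply(split(tChr, f),
                     function(v) length(unique(v)) <= 1, logical(1))
    oneOri <- vapply(split(ori[sh], f),
                     function(v) length(unique(v)) <= 1, logical(1))
    minS <- vapply(split(tS, f),
                   function(v) if (length(v)) min(v) else NA_real_,
                   numeric(1))
    maxE <- vapply(split(tE, f),
                   function(v) if (length(v)) max(v) else NA_real_,
                   numeric(1))
    firstChr <- vapply(split(tChr, f),
                       function(v) if (length(v)) v[1] else NA_character_,
                       character(1))
    okQ <- coveredBp / width(x) >= minMappedFraction & oneChr & oneOri &
      !is.na(minS)
    resChr[okQ] <- firstChr[okQ]
    resS[okQ] <- as.integer(minS[okQ])
    resE[okQ] <- as.integer(maxE[okQ])
  }
  mappedGr <- GRanges(resChr[okQ], IRanges(resS[okQ], resE[okQ]))
  part <- PartitioningByEnd(cumsum(as.integer(okQ)))
  grl <- relist(mappedGr, part)
  names(grl) <- names(x)
  grl
}

#' Invert a block coordinate map
#'
#' Swaps source and target blocks; orientation is unchanged (reversal is its
#' own inverse). Requires the target blocks to be non-overlapping.
#'
#' @param map a [BlockCoordinateMap-class].
#' @return The inverse [BlockCoordinateMap-class].
#' @export
invertBlockMap <- function(map) {
  blockCoordinateMap(targetBlocks(map), sourceBlocks(map),
                     blockOrientation(map))
}

# Collapse a GRangesList from mapIntervals to a GRanges + mapped flag.
flattenMapped <- function(grl) {
  mapped <- lengths(grl) == 1
  gr <- unlist(grl, use.names = FALSE)
  list(mapped = mapped, ranges = gr,
       index = which(mapped))
}
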