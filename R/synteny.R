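## Coordinate projection between species, reference and ancestral karyotype
## through syntenic fragments, by linear interpolation within each fragment.

.round_half_up <- function(x) floor(x + 0.5)

#' Project a coordinate through one syntenic fragment
#'
#' Linear interpolation of a source coordinate into destination coordinates:
#' for a co-oriented fragment,
#' `dst_start + (attr - src_start)/(src_end - src_start) * (dst_end -
#' dst_start)`; for an inverted fragment the same scaled offset is taken
#' from `dst_end` instead. The result is rounded half-up to integer bp and
#' always lies within the destination fragment. Coordinates here are
#' 0-based half-open, as stored in [SyntenyMap-class] block tables.
#'
#' @param block a single-row block (list or one-row data.frame with the
#'   SyntenyMap columns).
#' @param attribute source coordinate (bp) to project; must satisfy
#'   `src_start <= attribute <= src_end`.
#' @return destination coordinate (bp, 0-based).
#' @export
projectCoordinate <- function(block, attribute) {
  b <- as.list(block)
  if (any(attribute < b$src_start) || any(attribute > b$src_end))
    stop(sprintf("attribute outside fragment [%d, %d]",
                 as.integer(b$src_start), as.integer(b$src_end)))
  frac <- (attribute - b$src_start) / (b$src_end - b$src_start)
  off <- frac * (b$dst_end - b$dst_start)
  res <- if (identical(b$strand, "-")) b$dst_end - off else b$dst_start + off
  pmin(pmax(.round_half_up(res), b$dst_start), b$dst_end)
}

#' Project regions through a synteny map
#'
#' Each region is clipped to every overlapping syntenic fragment and its
#' endpoints projected per fragment; inverted fragments yield destination
#' intervals with start < end after swapping. Sub-intervals falling in
#' inter-fragment gaps are reported in `unmapped`, never silently dropped.
#'
#' @param regions `GRanges` on the source genome.
#' @param map a [SyntenyMap-class] from the source to the destination.
#' @return list with `mapped` (`GRanges` on the destination, with metadata
#'   columns `region` — index into `regions` — and `fragment` — source block
#'   row) and `unmapped` (`GRanges` of uncovered source sub-intervals, with
#'   `region`).
#' @export
projectRegions <- function(regions, map) {
  stopifnot(is(map, "SyntenyMap"))
  b <- syntenyBlocks(map)
  bg <- GRanges(b$src_chrom, IRanges(b$src_start + 1, b$src_end))
  GenomeInfoDb::seqlevels(bg) <-
    union(GenomeInfoDb::seqlevels(bg),
          as.character(GenomeInfoDb::seqlevels(regions)))
  regs <- granges(regions)
  GenomeInfoDb::seqlevels(regs) <- GenomeInfoDb::seqlevels(bg)
  hits <- findOverlaps(regs, bg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  mapped <- GRanges(region = integer(0), fragment = integer(0))
  if (length(hits)) {
    ## clip each region to each overlapping fragment (0-based half-open)
    cs <- pmax(start(regs)[qh] - 1, b$src_start[sh])
    ce <- pmin(end(regs)[qh], b$src_end[sh])
    frac1 <- (cs - b$src_start[sh]) / (b$src_end[sh] - b$src_start[sh])
    frac2 <- (ce - b$src_start[sh]) / (b$src_end[sh] - b$src_start[sh])
    span <- b$dst_end[sh] - b$dst_start[sh]
    plus <- b$strand[sh] == "+"
    p1 <- ifelse(plus, b$dst_start[sh] + frac1 * span,
                 b$dst_end[sh] - frac1 * span)
    p2 <- ifelse(plus, b$dst_start[sh] + frac2 * span,
                 b$dst_end[sh] - frac2 * span)
    p1 <- pmin(pmax(.round_half_up(p1), b$dst_start[sh]), b$dst_end[sh])
    p2 <- pmin(pmax(.round_half_up(p2), b$dst_start[sh]), b$dst_end[sh])
    ds <- pmin(p1, p2)
    de <- pmax(p1, p2)
    de[de == ds] <- ds[de == ds] + 1  # keep at least 1 bp after rounding
    mapped <- GRanges(b$dst_chrom[sh], IRanges(ds + 1, de),
                      region = qh, fragment = sh)
  }
  gaps <- GenomicRanges::subtract(regs, reduce(bg), ignore.strand = TRUE)
  ln <- lengths(gaps)
  unmapped <- unlist(gaps, use.names = FALSE)
  mcols(unmapped)$region <- rep(seq_along(regs), ln)
  noChrom <- setdiff(unique(as.character(seqnames(regs))[ln > 0 &
                       !(seq_along(regs) %in% qh)]),
                     unique(b$src_chrom))
  if (length(noChrom))
    warning("region chromosome(s) absent from synteny map: ",
            paste(noChrom, collapse = ", "))
  list(mapped = mapped, unmapped = unmapped)
}

#' @rdname projectRegions
#' @details `liftInterval()` is the species-to-species form of the same
#'   projection, used to carry windows and calls between extant genomes.
#' @export
liftInterval <- function(regions, map) projectRegions(regions, map)

#' Invert a synteny map
#'
#' Swaps the source and destination coordinate systems; fragment
#' orientation is preserved (the linear form is symmetric).
#'
#' @param map a [SyntenyMap-class].
#' @return the inverted [SyntenyMap-class].
#' @export
invertSyntenyMap <- function(map) {
  b <- syntenyBlocks(map)
  SyntenyMap(map@dst, map@src,
             data.frame(src_chrom = b$dst_chrom, src_start = b$dst_start,
                        src_end = b$dst_end, dst_chrom = b$src_chrom,
                        dst_start = b$src_start, dst_end = b$src_end,
                        strand = b$strand, stringsAsFactors = FALSE))
}

#' Compose two synteny maps (A->B then B->C)
#'
#' Intersects each A->B fragment with the B->C fragments on the shared
#' middle genome and projects the pieces, yielding a direct A->C map.
#'
#' @param mapAB,mapBC [SyntenyMap-class] objects sharing the middle genome.
#' @return a [SyntenyMap-class] from A to C.
#' @export
composeSyntenyMaps <- function(mapAB, mapBC) {
  ab <- syntenyBlocks(mapAB)
  bc <- syntenyBlocks(mapBC)
  rows <- list()
  for (i in seq_len(nrow(ab))) {
    hits <- which(bc$src_chrom == ab$dst_chrom[i] &
                  bc$src_start < ab$dst_end[i] &
                  bc$src_end > ab$dst_start[i])
    for (j in hits) {
      ms <- max(ab$dst_start[i], bc$src_start[j])
      me <- min(ab$dst_end[i], bc$src_end[j])
      ## back-project middle interval onto A
      a1 <- projectCoordinate(list(
        src_chrom = ab$dst_chrom[i], src_start = ab$dst_start[i],
        src_end = ab$dst_end[i], dst_chrom = ab$src_chrom[i],
        dst_start = ab$src_start[i], dst_end = ab$src_end[i],
        strand = ab$strand[i]), ms)
      a2 <- projectCoordinate(list(
        src_chrom = ab$dst_chrom[i], src_start = ab$dst_start[i],
        src_end = ab$dst_end[i], dst_chrom = ab$src_chrom[i],
        dst_start = ab$src_start[i], dst_end = ab$src_end[i],
        strand = ab$strand[i]), me)
      ## forward-project onto C
      c1 <- projectCoordinate(bc[j, ], ms)
      c2 <- projectCoordinate(bc[j, ], me)
      strand <- if (ab$strand[i] == bc$strand[j]) "+" else "-"
      rows[[length(rows) + 1L]] <- data.frame(
        src_chrom = ab$src_chrom[i], src_start = min(a1, a2),
        src_end = max(a1, a2), dst_chrom = bc$dst_chrom[j],
        dst_start = min(c1, c2), dst_end = max(c1, c2),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$src_end > out$src_start & out$dst_end > out$dst_start, ,
             drop = FALSE]
  SyntenyMap(mapAB@src, mapBC@dst, out)
}

#' Read / write synteny block tables
#'
#' Seven-column TSV (`src_chrom`, `src_start`, `src_end`, `dst_chrom`,
#' `dst_start`, `dst_end`, `strand`), coordinates 0-based half-open.
#'
#' @param path file path.
#' @param src,dst coordinate-system names recorded on the object.
#' @return [SyntenyMap-class] (read) or invisible path (write).
#' @export
readSyntenyTsv <- function(path, src = "src", dst = "dst") {
  b <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  SyntenyMap(src, dst, b)
}

#' @rdname readSyntenyTsv
#' @param map a [SyntenyMap-class] to write.
#' @export
writeSyntenyTsv <- function(map, path) {
  utils::write.table(syntenyBlocks(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
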