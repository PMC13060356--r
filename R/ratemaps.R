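## Window generation, sliding-block averaging, rate-to-window mapping,
## desert zero-filling, and genome-wide quartile categorisation.

#' Tile chromosomes into fixed-size windows
#'
#' Generates consecutive windows of `size` bp from the start of each
#' chromosome; the final window is truncated at the chromosome end and
#' retained. The default matches the 1.5 Mb windows used for cross-species
#' rate comparison.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp), or a
#'   two-column data.frame (name, length).
#' @param size window size in bp (default 1,500,000).
#' @return `GRanges` of windows with seqlengths set.
#' @export
makeWindows <- function(chromSizes, size = 1.5e6) {
  if (is.data.frame(chromSizes))
    chromSizes <- stats::setNames(as.numeric(chromSizes[[2]]),
                                  as.character(chromSizes[[1]]))
  if (size <= 0) stop("window size must be > 0")
  if (any(chromSizes <= 0)) stop("zero-length chromosome in chromSizes")
  parts <- lapply(names(chromSizes), function(chr) {
    L <- chromSizes[[chr]]
    starts <- seq(0, L - 1, by = size)
    data.frame(chr = chr, start = starts + 1,
               end = pmin(starts + size, L))
  })
  df <- do.call(rbind, parts)
  gr <- GRanges(df$chr, IRanges(df$start, df$end),
                seqinfo = Seqinfo(names(chromSizes),
                                  seqlengths = chromSizes))
  gr
}

#' Sliding-block averaging of a raw rate track
#'
#' Averages a raw recombination-rate track into overlapping blocks placed at
#' multiples of `step` (default 2 Mb blocks every 50 kb), the standard
#' post-processing applied to windowed rate estimates before downstream
#' comparison. Each block carries the unweighted mean of the raw interval
#' values overlapping it; terminal blocks are truncated at the chromosome
#' end. Missing raw values are ignored; blocks with no data are `NA`.
#'
#' @param rawMap a [RecombMap-class].
#' @param block block width in bp (default 2e6).
#' @param step distance between block starts in bp (default 5e4).
#' @param chromSizes optional named lengths; defaults to the extent of the
#'   raw data per chromosome.
#' @return A smoothed [RecombMap-class].
#' @export
slidingAverage <- function(rawMap, block = 2e6, step = 5e4,
                           chromSizes = NULL) {
  stopifnot(is(rawMap, "RecombMap"))
  if (!(block >= step && step > 0)) stop("need block >= step > 0")
  w <- rateWindows(rawMap)
  if (length(w) == 0L)
    return(RecombMap(mapSpecies(rawMap),
                     GRanges(rate = numeric(0)), "slidingAverage: empty"))
  if (is.null(chromSizes)) {
    chromSizes <- tapply(end(w), as.character(seqnames(w)), max)
    chromSizes <- stats::setNames(as.numeric(chromSizes), names(chromSizes))
  }
  parts <- lapply(names(chromSizes), function(chr) {
    L <- chromSizes[[chr]]
    starts <- seq(0, L - 1, by = step)
    data.frame(chr = chr, start = starts + 1,
               end = pmin(starts + block, L))
  })
  df <- do.call(rbind, parts)
  blocks <- GRanges(df$chr, IRanges(df$start, df$end))
  hits <- findOverlaps(blocks, w)
  vals <- mcols(w)$rate[S4Vectors::subjectHits(hits)]
  means <- rep(NA_real_, length(blocks))
  agg <- tapply(vals, S4Vectors::queryHits(hits),
                function(v) mean(v, na.rm = TRUE))
  means[as.integer(names(agg))] <- as.numeric(agg)
  means[is.nan(means)] <- NA_real_
  mcols(blocks)$rate <- means
  RecombMap(mapSpecies(rawMap), blocks,
            sprintf("slidingAverage(block=%g, step=%g) of [%s]",
                    block, step, rawMap@provenance))
}

#' Map a rate track onto target windows
#'
#' Each window receives the unweighted mean of the source-interval rates
#' overlapping it (the common default of interval-map tooling; set
#' `weighted = TRUE` for an overlap-length-weighted mean). Windows with no
#' overlapping source data are `NA`; window chromosomes absent from the map
#' trigger a warning and yield all-`NA` windows.
#'
#' @param map a [RecombMap-class] (source intervals).
#' @param windows `GRanges` of target windows.
#' @param weighted use overlap-length weighting instead of the unweighted
#'   mean.
#' @return A windowed [RecombMap-class] on `windows`.
#' @export
mapRatesToWindows <- function(map, windows, weighted = FALSE) {
  stopifnot(is(map, "RecombMap"))
  src <- rateWindows(map)
  miss <- setdiff(unique(as.character(seqnames(windows))),
                  unique(as.character(seqnames(src))))
  if (length(miss))
    warning("chromosome(s) absent from rate map: ",
            paste(miss, collapse = ", "))
  src <- src[!is.na(mcols(src)$rate)]
  out <- granges(windows)
  hits <- findOverlaps(out, src)
  qh <- S4Vectors::queryHits(hits)
  vals <- mcols(src)$rate[S4Vectors::subjectHits(hits)]
  means <- rep(NA_real_, length(out))
  if (length(hits)) {
    if (weighted) {
      ov <- width(pintersect(out[qh], src[S4Vectors::subjectHits(hits)]))
      means[unique(qh)] <- as.numeric(
        tapply(vals * ov, qh, sum) / tapply(ov, qh, sum))
    } else {
      agg <- tapply(vals, qh, mean)
      means[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  mcols(out)$rate <- means
  RecombMap(mapSpecies(map), out,
            sprintf("mapRatesToWindows(weighted=%s) of [%s]",
                    weighted, map@provenance))
}

#' Zero-fill data-free windows inside recombination deserts
#'
#' Windows with a missing rate that fall inside a designated desert region
#' (e.g. the low-divergence desert in the middle of the X chromosome) are
#' set to 0; windows that carry data, and missing windows outside deserts,
#' are unchanged.
#'
#' @param map a [RecombMap-class].
#' @param desertRegions `GRanges` of desert intervals.
#' @return A [RecombMap-class] with deserts zero-filled.
#' @export
fillDesertZero <- function(map, desertRegions) {
  stopifnot(is(map, "RecombMap"))
  w <- rateWindows(map)
  r <- mcols(w)$rate
  inDesert <- overlapsAny(w, desertRegions)
  r[is.na(r) & inDesert] <- 0
  mcols(w)$rate <- r
  RecombMap(mapSpecies(map), w,
            sprintf("fillDesertZero of [%s]", map@provenance))
}

#' Assign genome-wide recombination-rate quartiles
#'
#' Non-missing windows are ranked from highest to lowest rate genome-wide
#' (per species, one list across chromosomes) and divided into four rate
#' categories of as-equal-as-possible size; Q4 holds the highest rates and
#' Q1 the lowest, with any remainder going to the higher categories first.
#' Ties in rate are broken by (chromosome, start) for determinism; an
#' all-equal track is degenerate and flagged with a warning. Missing windows
#' carry no category.
#'
#' @param map a windowed [RecombMap-class].
#' @return A [QuartileTrack-class] on the same windows.
#' @export
assignQuartiles <- function(map) {
  stopifnot(is(map, "RecombMap"))
  w <- rateWindows(map)
  r <- mcols(w)$rate
  ok <- which(!is.na(r))
  n <- length(ok)
  if (n < 4L) stop("need >= 4 non-missing windows to assign quartiles")
  if (length(unique(r[ok])) == 1L)
    warning("all rates equal: quartiles determined solely by coordinate ",
            "tie-break (degenerate track)")
  ## descending rate, ties by genomic coordinate
  o <- ok[order(-r[ok], as.character(seqnames(w))[ok], start(w)[ok])]
  base <- n %/% 4L
  rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= rem)  # Q4 gets remainder first
  cats <- rep(c("Q4", "Q3", "Q2", "Q1"), times = sizes)
  category <- factor(rep(NA_character_, length(w)), levels = QUARTILE_LEVELS)
  category[o] <- cats
  out <- granges(w)
  mcols(out)$category <- category
  mcols(out)$rate <- r
  QuartileTrack(mapSpecies(map), out)
}
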