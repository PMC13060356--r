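suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## a windowed rate map from explicit vectors
mkMap <- function(rates, chrom = "chr1", width = 10, species = "spX") {
  n <- length(rates)
  gr <- GRanges(chrom, IRanges(start = (seq_len(n) - 1) * width + 1,
                               width = width), rate = rates)
  RecombMap(species, gr, "fixture")
}

## a quartile track from explicit categories
mkTrack <- function(categories, chrom = "chr1", width = 10,
                    species = "spX") {
  n <- length(categories)
  gr <- GRanges(chrom, IRanges(start = (seq_len(n) - 1) * width + 1,
                               width = width),
                category = factor(categories,
                                  levels = c("Q1", "Q2", "Q3", "Q4")))
  QuartileTrack(species, gr)
}

## one-block synteny map, 0-based half-open coordinates
mkBlock <- function(srcChrom, srcStart, srcEnd, dstChrom, dstStart, dstEnd,
                    strand = "+") {
  data.frame(src_chrom = srcChrom, src_start = srcStart, src_end = srcEnd,
             dst_chrom = dstChrom, dst_start = dstStart, dst_end = dstEnd,
             strand = strand, stringsAsFactors = FALSE)
}

identityMap <- function(chromSizes, src = "A", dst = "B") {
  SyntenyMap(src, dst, do.call(rbind, lapply(names(chromSizes), function(ch)
    mkBlock(ch, 0, chromSizes[[ch]], ch, 0, chromSizes[[ch]]))))
}

## small simulation config for unit tests (two long + one short chromosome)
tinyConfig <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         ancestralChromosomes = c(A1 = 36e6, A2 = 27e6, A3 = 8e6),
         nPlantedCold = 3, nPlantedHot = 3,
         nFissions = 1, nFusions = 1, nInversions = 1,
         shortChromThreshold = 1e7, geneCount = 200),
    list(...))
  do.call(simConfig, args)
}

## brute-force interval merge oracle (union-find style sweep)
bruteMerge <- function(df, maxGap) {
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - cur$end <= maxGap) {
        cur$end <- max(cur$end, d$end[i])
        cur$support <- max(cur$support, d$support[i])
      } else {
        out[[length(out) + 1]] <- cur
        cur <- d[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

## brute-force region classification oracle (direct transcription of the
## 50%-mixture rule)
bruteClassify <- function(cats) {
  cats <- cats[!is.na(cats)]
  if (!length(cats)) return("none")
  nl <- sum(cats %in% c("Q1", "Q2"))
  nh <- sum(cats %in% c("Q3", "Q4"))
  if (nl > nh) "low" else if (nh > nl) "high" else "none"
}
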