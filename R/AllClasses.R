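#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps reduce granges sort
#' @importFrom IRanges IRanges subsetByOverlaps pintersect overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo seqinfo<- Seqinfo
NULL

QUARTILE_LEVELS <- c("Q1", "Q2", "Q3", "Q4")

#' RecombMap: a per-species windowed recombination-rate track
#'
#' Ordered genomic intervals carrying a recombination-rate estimate
#' (`rate` metadata column, `NA` where no data are available). Windowed
#' tracks are non-overlapping; sliding-block-averaged tracks overlap by
#' construction (blocks wider than their step). Coordinates follow the
#' usual GRanges 1-based closed convention in memory; all on-disk formats
#' (bedGraph/BED) are 0-based half-open.
#'
#' @slot species species name.
#' @slot windows `GRanges` with a numeric `rate` metadata column.
#' @slot provenance free-text description of how the track was produced.
#' @export
setClass("RecombMap",
  representation(species = "character", windows = "GRanges",
                 provenance = "character"))

setValidity("RecombMap", function(object) {
  w <- object@windows
  if (is.null(mcols(w)$rate)) return("windows must carry a 'rate' column")
  if (!is.numeric(mcols(w)$rate)) return("'rate' must be numeric")
  r <- mcols(w)$rate
  if (any(r < 0, na.rm = TRUE)) return("rates must be >= 0 where present")
  if (length(object@species) != 1L) return("species must be a single name")
  if (length(w) > 1L) {
    o <- order(as.character(seqnames(w)), start(w))
    if (!identical(o, seq_along(w)))
      return("windows must be sorted by (chrom, start)")
  }
  TRUE
})

#' Construct a RecombMap
#'
#' @param species species name.
#' @param windows `GRanges` with a numeric `rate` metadata column; sorted
#'   automatically.
#' @param provenance free text recorded with the object.
#' @return A [RecombMap-class] object.
#' @export
RecombMap <- function(species, windows, provenance = "unspecified") {
  windows <- windows[order(as.character(seqnames(windows)), start(windows))]
  new("RecombMap", species = as.character(species), windows = windows,
      provenance = as.character(provenance))
}

#' QuartileTrack: per-species window-level rate category
#'
#' Each window carries a `category` in Q1..Q4 (Q1 = lowest rates) assigned by
#' genome-wide ranking, or `NA` where the underlying rate was missing.
#'
#' @slot species species name.
#' @slot windows `GRanges` with a `category` factor column (levels Q1..Q4).
#' @export
setClass("QuartileTrack",
  representation(species = "character", windows = "GRanges"))

setValidity("QuartileTrack", function(object) {
  cat <- mcols(object@windows)$category
  if (is.null(cat)) return("windows must carry a 'category' column")
  if (!is.factor(cat) || !identical(levels(cat), QUARTILE_LEVELS))
    return("'category' must be a factor with levels Q1..Q4")
  TRUE
})

QuartileTrack <- function(species, windows) {
  new("QuartileTrack", species = as.character(species), windows = windows)
}

#' SyntenyMap: collinear fragments linking two coordinate systems
#'
#' A table of syntenic fragments mapping a source genome onto a destination
#' genome (a reference species or the reconstructed ancestral karyotype).
#' Block coordinates are stored 0-based half-open, matching the synteny TSV
#' interchange format and the linear-interpolation projection formula.
#'
#' @slot src source species name.
#' @slot dst destination name (species or "ancestor").
#' @slot blocks `data.frame` with columns `src_chrom`, `src_start`,
#'   `src_end`, `dst_chrom`, `dst_start`, `dst_end`, `strand`.
#' @export
setClass("SyntenyMap",
  representation(src = "character", dst = "character", blocks = "data.frame"))

.SYNTENY_COLS <- c("src_chrom", "src_start", "src_end",
                   "dst_chrom", "dst_start", "dst_end", "strand")

setValidity("SyntenyMap", function(object) {
  b <- object@blocks
  if (!all(.SYNTENY_COLS %in% names(b)))
    return(paste("blocks must have columns:",
                 paste(.SYNTENY_COLS, collapse = ", ")))
  if (nrow(b) == 0L) return(TRUE)
  if (any(b$src_end <= b$src_start)) return("src_end must exceed src_start")
  if (any(b$dst_end <= b$dst_start)) return("dst_end must exceed dst_start")
  if (!all(b$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  TRUE
})

#' Construct a SyntenyMap
#'
#' @param src,dst names of the source and destination coordinate systems.
#' @param blocks block table (see [SyntenyMap-class]); coordinates 0-based
#'   half-open.
#' @return A [SyntenyMap-class] object.
#' @export
SyntenyMap <- function(src, dst, blocks) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  rownames(blocks) <- NULL
  new("SyntenyMap", src = as.character(src), dst = as.character(dst),
      blocks = blocks)
}

#' ConservedCalls: ALR/AHR calls on a reference genome
#'
#' @slot calls `GRanges` with metadata columns `class` ("ALR" or "AHR"),
#'   `support` (count of agreeing species) and `provenance`.
#' @export
setClass("ConservedCalls", representation(calls = "GRanges"))

setValidity("ConservedCalls", function(object) {
  m <- mcols(object@calls)
  if (is.null(m$class) || is.null(m$support))
    return("calls must carry 'class' and 'support' columns")
  if (!all(m$class %in% c("ALR", "AHR")))
    return("class must be 'ALR' or 'AHR'")
  if (length(object@calls) && any(m$support < 1))
    return("support must be >= 1")
  TRUE
})

ConservedCalls <- function(calls) new("ConservedCalls", calls = calls)

## ---- generics & accessors ---------------------------------------------

#' @rdname RecombMap-class
#' @param x an object with a species slot.
#' @export
setGeneric("mapSpecies", function(x) standardGeneric("mapSpecies"))

#' @rdname RecombMap-class
#' @export
setMethod("mapSpecies", "RecombMap", function(x) x@species)

#' @rdname QuartileTrack-class
#' @export
setMethod("mapSpecies", "QuartileTrack", function(x) x@species)

#' @rdname RecombMap-class
#' @export
setGeneric("rateWindows", function(x) standardGeneric("rateWindows"))

#' @rdname RecombMap-class
#' @export
setMethod("rateWindows", "RecombMap", function(x) x@windows)

#' @rdname QuartileTrack-class
#' @export
setMethod("rateWindows", "QuartileTrack", function(x) x@windows)

#' @rdname SyntenyMap-class
#' @param x a SyntenyMap.
#' @export
setGeneric("syntenyBlocks", function(x) standardGeneric("syntenyBlocks"))

#' @rdname SyntenyMap-class
#' @export
setMethod("syntenyBlocks", "SyntenyMap", function(x) x@blocks)

#' @rdname ConservedCalls-class
#' @param x a ConservedCalls object.
#' @export
setGeneric("callRanges", function(x) standardGeneric("callRanges"))

#' @rdname ConservedCalls-class
#' @export
setMethod("callRanges", "ConservedCalls", function(x) x@calls)

setMethod("show", "RecombMap", function(object) {
  r <- mcols(object@windows)$rate
  cat("RecombMap for", object@species, "—", length(object@windows),
      "windows on", length(unique(seqnames(object@windows))),
      "chromosome(s);", sum(is.na(r)), "missing\n")
  cat("provenance:", object@provenance, "\n")
})

setMethod("show", "QuartileTrack", function(object) {
  cat("QuartileTrack for", object@species, "—",
      length(object@windows), "windows:",
      paste(sprintf("%s=%d", QUARTILE_LEVELS,
                    as.integer(table(mcols(object@windows)$category))),
            collapse = " "), "\n")
})

setMethod("show", "SyntenyMap", function(object) {
  cat("SyntenyMap", object@src, "->", object@dst, "—",
      nrow(object@blocks), "blocks\n")
})

setMethod("show", "ConservedCalls", function(object) {
  tab <- table(factor(mcols(object@calls)$class, c("ALR", "AHR")))
  cat("ConservedCalls —", tab[["ALR"]], "ALR,", tab[["AHR"]], "AHR\n")
})

#' @rdname ConservedCalls-class
#' @param ... unused.
#' @export
setMethod("length", "ConservedCalls", function(x) length(x@calls))
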