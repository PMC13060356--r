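## Readers and writers for the interchange formats: bedGraph rate tracks,
## chromosome sizes, quartile BED, GFF3 genes, orthogroup TSV, ground truth
## JSON. All on-disk interval formats are 0-based half-open.

#' Read / write bedGraph recombination-rate tracks
#'
#' Parsing and serialisation are delegated to rtracklayer; the `score`
#' column is interpreted as the recombination rate. Windows with a missing
#' rate are dropped on write (bedGraph has no missing-value encoding);
#' re-mapping onto windows restores explicit missingness.
#'
#' @param path file path.
#' @param species species name recorded on the object.
#' @return a [RecombMap-class] (read); invisible path (write).
#' @export
readBedGraph <- function(path, species = "unknown") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  mcols(gr)$rate <- as.numeric(mcols(gr)$score)
  mcols(gr)$score <- NULL
  RecombMap(species, gr, sprintf("read from %s", basename(path)))
}

#' @rdname readBedGraph
#' @param map a [RecombMap-class] to write.
#' @export
writeBedGraph <- function(map, path) {
  gr <- rateWindows(map)
  gr <- gr[!is.na(mcols(gr)$rate)]
  mcols(gr)$score <- mcols(gr)$rate
  mcols(gr)$rate <- NULL
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write chromosome size tables
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector (read); invisible path (write).
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' @rdname readChromSizes
#' @param sizes named numeric vector of lengths.
#' @export
writeChromSizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a quartile track as 4-column BED
#'
#' Category goes in the BED name field; uncategorized windows are omitted.
#'
#' @param track a [QuartileTrack-class].
#' @param path output path.
#' @return invisible path.
#' @export
writeQuartileBed <- function(track, path) {
  w <- rateWindows(track)
  w <- w[!is.na(mcols(w)$category)]
  df <- data.frame(as.character(seqnames(w)), start(w) - 1L, end(w),
                   as.character(mcols(w)$category))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write gene annotations (GFF3, gene features)
#'
#' @param genes `GRanges` with a `symbol` column.
#' @param path file path.
#' @return `GRanges` with `symbol` (read); invisible path (write).
#' @export
writeGenesGff3 <- function(genes, path) {
  g <- granges(genes)
  mcols(g)$type <- "gene"
  mcols(g)$source <- "ancestralRecomb"
  mcols(g)$Name <- mcols(genes)$symbol
  mcols(g)$ID <- mcols(genes)$symbol
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGenesGff3
#' @export
readGenesGff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[as.character(mcols(g)$type) == "gene"]
  out <- granges(g)
  mcols(out)$symbol <- as.character(mcols(g)$Name)
  out
}

#' Read / write orthogroup tables
#'
#' Long-format TSV with columns `orthogroup`, `species`, `symbol`.
#'
#' @param path file path.
#' @return data.frame (read); invisible path (write).
#' @export
readOrthogroupsTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname readOrthogroupsTsv
#' @param orthogroups data.frame to write.
#' @export
writeOrthogroupsTsv <- function(orthogroups, path) {
  utils::write.table(orthogroups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the planted ground truth as JSON
#'
#' Records the planted calls (ancestor coordinates and class), their
#' per-species projections, and the rearrangement log.
#'
#' @param karyo result of [simulateKaryotypes()].
#' @param path output path.
#' @return invisible path.
#' @export
writeGroundTruthJson <- function(karyo, path) {
  gr2df <- function(g) data.frame(
    chrom = as.character(seqnames(g)), start = start(g) - 1L,
    end = end(g),
    class = if (!is.null(mcols(g)$class)) mcols(g)$class else NA)
  obj <- list(
    planted = data.frame(karyo$planted),
    perSpecies = lapply(karyo$groundTruth$perSpecies, gr2df),
    rearrangements = karyo$rearrangements)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
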