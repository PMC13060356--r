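## Classification of collinear regions, cross-species consensus ALR/AHR
## calling, merging of nearby calls and ALR/AHR overlap resolution.

#' Classify a collinear region from its window categories
#'
#' A region is classified from the ordered rate categories of its windows in
#' one species: the low set is \{Q1, Q2\} (the low extreme and the next
#' category above) and the high set \{Q3, Q4\}. If all categorized windows
#' fall in one set the region takes that class; if both sets are present the
#' class covering at least 50\% of the windows wins; an exact 50/50 tie is
#' ambiguous and yields `"none"`. By default the fraction is counted in
#' windows; supply `weights` (e.g. window widths) for a bp-weighted mode.
#'
#' @param categories character/factor vector of window categories (Q1..Q4;
#'   `NA` = uncategorized, ignored).
#' @param lowSet,highSet category sets defining the two classes.
#' @param weights optional non-negative weights, same length as
#'   `categories`.
#' @return `"low"`, `"high"` or `"none"`.
#' @export
classifyRegion <- function(categories, lowSet = c("Q1", "Q2"),
                           highSet = c("Q3", "Q4"), weights = NULL) {
  categories <- as.character(categories)
  if (is.null(weights)) weights <- rep(1, length(categories))
  keep <- !is.na(categories)
  categories <- categories[keep]
  weights <- weights[keep]
  if (length(categories) == 0L) return("none")
  wLow <- sum(weights[categories %in% lowSet])
  wHigh <- sum(weights[categories %in% highSet])
  if (wHigh == 0) return("low")
  if (wLow == 0) return("high")
  if (wLow == wHigh) return("none")
  if (wLow > wHigh) "low" else "high"
}

#' Cross-species consensus for one region
#'
#' Emits a conserved call when at least `minSupport` of the `nSpecies`
#' species share the same non-none class: low consensus becomes an ALR
#' (ancestrally low recombining) call, high an AHR call.
#'
#' @param perSpeciesClasses named character vector over species, values in
#'   `c("low", "high", "none")`.
#' @param minSupport minimum number of agreeing species (default 3).
#' @param nSpecies number of species expected (default 4).
#' @return `NULL`, or a list with `class` ("ALR"/"AHR") and `support`.
#' @export
consensusCall <- function(perSpeciesClasses, minSupport = 3L, nSpecies = 4L) {
  if (nSpecies < minSupport) stop("nSpecies must be >= minSupport")
  if (length(perSpeciesClasses) < nSpecies)
    stop(sprintf("expected %d species, got %d", nSpecies,
                 length(perSpeciesClasses)))
  nLow <- sum(perSpeciesClasses == "low")
  nHigh <- sum(perSpeciesClasses == "high")
  if (nLow >= minSupport) list(class = "ALR", support = nLow)
  else if (nHigh >= minSupport) list(class = "AHR", support = nHigh)
  else NULL
}

#' Merge nearby same-class calls
#'
#' Calls of one class on the same reference chromosome are merged into their
#' union when the gap between them is at most `maxGap` (default 1 Mb). The
#' support of a merged call is the maximum of its constituents. The
#' operation is idempotent.
#'
#' @param calls `GRanges` with `class` and `support` metadata columns; all
#'   one class.
#' @param maxGap largest gap (bp) still merged.
#' @return merged `GRanges`.
#' @export
mergeCalls <- function(calls, maxGap = 1e6) {
  if (length(calls) == 0L) return(calls)
  cls <- unique(mcols(calls)$class)
  if (length(cls) != 1L) stop("mergeCalls requires a single class")
  calls <- calls[order(as.character(seqnames(calls)), start(calls))]
  merged <- reduce(granges(calls), min.gapwidth = maxGap + 1,
                   with.revmap = TRUE)
  sup <- vapply(mcols(merged)$revmap,
                function(ix) max(mcols(calls)$support[ix]), numeric(1))
  out <- granges(merged)
  mcols(out)$class <- cls
  mcols(out)$support <- sup
  out[order(as.character(seqnames(out)), start(out))]
}

#' Resolve overlaps between ALR and AHR call sets
#'
#' A partial overlap between an ALR and an AHR call is cut at the integer
#' midpoint of the overlapped interval, each call keeping its own side. A
#' call fully contained in a call of the other class is dropped and logged.
#' The returned classes are mutually disjoint.
#'
#' @param alrCalls,ahrCalls `GRanges` with `class`/`support` columns, each
#'   internally non-overlapping (post-merge).
#' @return list with `alr`, `ahr` and `log` (data.frame of events).
#' @export
resolveOverlaps <- function(alrCalls, ahrCalls) {
  log <- data.frame(event = character(0), detail = character(0))
  dropA <- logical(length(alrCalls))
  dropH <- logical(length(ahrCalls))
  hits <- findOverlaps(alrCalls, ahrCalls)
  for (k in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[k]
    j <- S4Vectors::subjectHits(hits)[k]
    as0 <- start(alrCalls)[i] - 1L; ae0 <- end(alrCalls)[i]
    hs0 <- start(ahrCalls)[j] - 1L; he0 <- end(ahrCalls)[j]
    if (hs0 >= as0 && he0 <= ae0) {           # AHR contained in ALR
      dropH[j] <- TRUE
      log <- rbind(log, data.frame(event = "contained_dropped",
        detail = sprintf("AHR [%d,%d) inside ALR [%d,%d)",
                         hs0, he0, as0, ae0)))
    } else if (as0 >= hs0 && ae0 <= he0) {    # ALR contained in AHR
      dropA[i] <- TRUE
      log <- rbind(log, data.frame(event = "contained_dropped",
        detail = sprintf("ALR [%d,%d) inside AHR [%d,%d)",
                         as0, ae0, hs0, he0)))
    } else {
      o0 <- max(as0, hs0); o1 <- min(ae0, he0)
      mid <- .round_half_up((o0 + o1) / 2)
      if (as0 < hs0) {                        # ALR on the left
        end(alrCalls)[i] <- mid
        start(ahrCalls)[j] <- mid + 1L
      } else {
        end(ahrCalls)[j] <- mid
        start(alrCalls)[i] <- mid + 1L
      }
      log <- rbind(log, data.frame(event = "midpoint_cut",
        detail = sprintf("overlap [%d,%d) cut at %d", o0, o1, mid)))
    }
  }
  list(alr = alrCalls[!dropA], ahr = ahrCalls[!dropH], log = log)
}

.maximal_runs <- function(idx) {
  ## split a sorted integer index vector into maximal consecutive runs
  if (length(idx) == 0L) return(list())
  split(idx, cumsum(c(1L, diff(idx) != 1L)))
}

.classify_lifted_batch <- function(regions, track, map) {
  ## lift reference regions into one species in a single projection and
  ## classify each region's overlapped windows
  tw <- rateWindows(track)
  out <- rep("none", length(regions))
  if (is.null(map)) {
    hits <- findOverlaps(regions, tw)
    regIdx <- S4Vectors::queryHits(hits)
    winIdx <- S4Vectors::subjectHits(hits)
  } else {
    proj <- projectRegions(regions, map)
    if (length(proj$mapped) == 0L) return(out)
    hits <- findOverlaps(proj$mapped, tw)
    regIdx <- mcols(proj$mapped)$region[S4Vectors::queryHits(hits)]
    winIdx <- S4Vectors::subjectHits(hits)
    keep <- !duplicated(cbind(regIdx, winIdx))  # pieces can share windows
    regIdx <- regIdx[keep]
    winIdx <- winIdx[keep]
  }
  if (!length(regIdx)) return(out)
  cats <- as.character(mcols(tw)$category)[winIdx]
  byRegion <- split(cats, regIdx)
  out[as.integer(names(byRegion))] <-
    vapply(byRegion, classifyRegion, character(1))
  out
}

#' Call ancestrally conserved low/high recombining regions
#'
#' Orchestrates the consensus pipeline on one reference genome: maximal runs
#' of reference windows whose categories lie in the low set (or high set)
#' define candidate collinear regions; each region is lifted into every
#' other species through its synteny map, classified per species, and a
#' consensus call is taken. Calls of one class within `maxGap` are merged
#' and ALR/AHR overlaps resolved at the overlap midpoint. A curation
#' override may force inclusions or exclusions (replacing by-hand review
#' with an auditable input).
#'
#' @param tracks named list of [QuartileTrack-class], one per species.
#' @param syntenyFromRef named list of [SyntenyMap-class] mapping the
#'   reference genome to each non-reference species.
#' @param reference name of the reference species (must be in `tracks`).
#' @param minSupport,nSpecies consensus parameters (defaults 3 of 4).
#' @param lowSet,highSet category sets (defaults \{Q1,Q2\} / \{Q3,Q4\}).
#' @param maxGap merge gap in bp (default 1e6).
#' @param curation optional list with `exclude` (`GRanges`; overlapping
#'   calls dropped) and/or `include` (`GRanges` with `class` and `support`
#'   columns; appended before merging).
#' @return a [ConservedCalls-class]; the resolution log is in
#'   `metadata(callRanges(x))$log`.
#' @export
callConservedRegions <- function(tracks, syntenyFromRef, reference,
                                 minSupport = 3L, nSpecies = length(tracks),
                                 lowSet = c("Q1", "Q2"),
                                 highSet = c("Q3", "Q4"),
                                 maxGap = 1e6, curation = NULL) {
  stopifnot(reference %in% names(tracks))
  if (length(tracks) < nSpecies) stop("fewer tracks than nSpecies")
  refw <- rateWindows(tracks[[reference]])
  refw <- refw[order(as.character(seqnames(refw)), start(refw))]
  cats <- as.character(mcols(refw)$category)
  others <- setdiff(names(tracks), reference)
  ## enumerate maximal extreme-or-adjacent runs for both classes
  chrom <- as.character(seqnames(refw))
  regionL <- list()
  for (class in c("low", "high")) {
    set <- if (class == "low") lowSet else highSet
    runs <- .maximal_runs(which(cats %in% set))
    runs <- unlist(lapply(runs, function(ix)
      split(ix, chrom[ix])), recursive = FALSE, use.names = FALSE)
    for (ix in runs)
      regionL[[length(regionL) + 1L]] <- data.frame(
        chrom = chrom[ix[1]], start = min(start(refw)[ix]),
        end = max(end(refw)[ix]), class = class,
        refClass = classifyRegion(cats[ix], lowSet, highSet))
  }
  empty <- GRanges(class = character(0), support = numeric(0))
  calls <- empty
  if (length(regionL)) {
    rdf <- do.call(rbind, regionL)
    regions <- GRanges(rdf$chrom, IRanges(rdf$start, rdf$end))
    liftM <- vapply(others, function(sp)
      .classify_lifted_batch(regions, tracks[[sp]], syntenyFromRef[[sp]]),
      character(length(regions)))
    if (length(regions) == 1L)
      liftM <- matrix(liftM, nrow = 1L)
    perSpecies <- cbind(matrix(rdf$refClass, ncol = 1L), liftM)
    colnames(perSpecies) <- c(reference, others)
    keepL <- list()
    for (i in seq_along(regions)) {
      cc <- consensusCall(stats::setNames(perSpecies[i, ],
                                          colnames(perSpecies)),
                          minSupport, nSpecies)
      if (!is.null(cc) &&
          cc$class == ifelse(rdf$class[i] == "low", "ALR", "AHR")) {
        g <- regions[i]
        mcols(g)$class <- cc$class
        mcols(g)$support <- cc$support
        keepL[[length(keepL) + 1L]] <- g
      }
    }
    if (length(keepL))
      calls <- suppressWarnings(do.call(c, keepL))
  }
  if (!is.null(curation$include))
    calls <- c(calls, curation$include[, c("class", "support")])
  if (!is.null(curation$exclude) && length(calls))
    calls <- calls[!overlapsAny(calls, curation$exclude)]
  alr <- calls[mcols(calls)$class == "ALR"]
  ahr <- calls[mcols(calls)$class == "AHR"]
  if (length(alr)) alr <- mergeCalls(alr, maxGap)
  if (length(ahr)) ahr <- mergeCalls(ahr, maxGap)
  res <- resolveOverlaps(alr, ahr)
  out <- suppressWarnings(c(res$alr, res$ahr))
  out <- out[order(as.character(seqnames(out)), start(out))]
  metadata(out)$log <- res$log
  metadata(out)$reference <- reference
  ConservedCalls(out)
}

#' Write conserved calls as BED6
#'
#' One file per class is conventional; here a single BED6 is written with
#' `name = class:support` and `score = support`.
#'
#' @param x a [ConservedCalls-class].
#' @param path output path.
#' @return invisible path.
#' @export
writeCallsBed <- function(x, path) {
  g <- callRanges(x)
  df <- data.frame(chrom = as.character(seqnames(g)), start = start(g) - 1L,
                   end = end(g),
                   name = sprintf("%s:%d", mcols(g)$class,
                                  as.integer(mcols(g)$support)),
                   score = as.integer(mcols(g)$support), strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
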