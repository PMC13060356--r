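## Gene-level analysis: LOC symbol resolution by ortholog vote, gene to
## rate-category assignment, shared gene sets, and retention summaries.

#' Resolve LOC placeholder symbols through orthogroups
#'
#' Unnamed annotations ("LOC" + integer) are renamed when their orthogroup
#' carries a proper symbol in a designated anchor species (default anchors:
#' human, dog, mouse) or the same proper symbol in at least two species.
#' Conflicting candidate names, or a LOC appearing in more than one
#' orthogroup, leave the symbol unresolved (logged).
#'
#' @param orthogroups long-format data.frame with columns `orthogroup`,
#'   `species`, `symbol`.
#' @param genes data.frame of gene records with columns `species`, `symbol`
#'   (others carried through).
#' @param anchors species whose single vote suffices.
#' @return list with `genes` (renamed table) and `unresolved` (data.frame
#'   of LOC symbols left as-is, with reason).
#' @export
resolveLocSymbols <- function(orthogroups, genes,
                              anchors = c("human", "dog", "mouse")) {
  isLoc <- function(s) grepl("^LOC[0-9]+$", s)
  unresolved <- data.frame(symbol = character(0), reason = character(0))
  lut <- character(0)  # LOC symbol -> resolved name
  locs <- unique(orthogroups$symbol[isLoc(orthogroups$symbol)])
  for (loc in locs) {
    ogs <- unique(orthogroups$orthogroup[orthogroups$symbol == loc])
    if (length(ogs) > 1L) {
      unresolved <- rbind(unresolved, data.frame(
        symbol = loc, reason = "multiple orthogroups"))
      next
    }
    members <- orthogroups[orthogroups$orthogroup == ogs, , drop = FALSE]
    named <- members[!isLoc(members$symbol), , drop = FALSE]
    if (nrow(named) == 0L) {
      unresolved <- rbind(unresolved, data.frame(
        symbol = loc, reason = "no named ortholog"))
      next
    }
    counts <- table(named$symbol)
    qualifies <- vapply(names(counts), function(nm) {
      sp <- named$species[named$symbol == nm]
      any(sp %in% anchors) || length(unique(sp)) >= 2L
    }, logical(1))
    cands <- names(counts)[qualifies]
    if (length(cands) == 1L) {
      lut[loc] <- cands
    } else if (length(cands) == 0L) {
      unresolved <- rbind(unresolved, data.frame(
        symbol = loc, reason = "no qualifying ortholog"))
    } else {
      unresolved <- rbind(unresolved, data.frame(
        symbol = loc, reason = "conflicting candidate names"))
    }
  }
  hit <- genes$symbol %in% names(lut)
  genes$symbol[hit] <- unname(lut[genes$symbol[hit]])
  list(genes = genes, unresolved = unresolved, renames = lut)
}

#' Assign genes to recombination-rate categories
#'
#' Each gene takes the category of the windows it overlaps in that species'
#' quartile track: the majority category by overlapped-window count, with
#' ties resolved by a seeded uniform random choice among the tied
#' categories (so a gene straddling a boundary between two equally
#' represented categories is assigned to either with probability 1/2).
#' Genes overlapping no categorized window are unassigned (`NA`).
#'
#' @param genes `GRanges` of gene spans with a `symbol` metadata column.
#' @param track a [QuartileTrack-class] for the same species.
#' @param seed integer seed for tie resolution.
#' @return `genes` with a `category` metadata column added.
#' @export
assignGeneCategories <- function(genes, track, seed = 1L) {
  tw <- rateWindows(track)
  tw <- tw[!is.na(mcols(tw)$category)]
  hits <- findOverlaps(genes, tw)
  catOf <- split(as.character(mcols(tw)$category)[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits), seq_along(genes)))
  rng <- .seeded_rng(seed)
  category <- vapply(seq_along(genes), function(i) {
    cats <- catOf[[i]]
    if (length(cats) == 0L) return(NA_character_)
    tab <- table(cats)
    top <- sort(names(tab)[tab == max(tab)])
    if (length(top) == 1L) return(top)
    top[rng$int(length(top))]
  }, character(1))
  mcols(genes)$category <- factor(category, levels = QUARTILE_LEVELS)
  genes
}

## tiny deterministic RNG stream independent of the global .Random.seed
.seeded_rng <- function(seed) {
  state <- as.numeric(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  list(int = function(n) {
    state <<- (state * 16807) %% 2147483647  # Lehmer step
    1L + as.integer(state %% n)
  })
}

#' Genes shared and categorized across all species
#'
#' Returns symbols present, single-copy, and carrying a rate category in
#' every supplied species; within-species duplicate symbols are excluded.
#'
#' @param geneTables named list (per species) of data.frames with columns
#'   `symbol` and `category`.
#' @return character vector of shared symbols.
#' @export
sharedGeneSet <- function(geneTables) {
  if (length(geneTables) < 2L) stop("need >= 2 species")
  sets <- lapply(geneTables, function(tb) {
    tb <- tb[!is.na(tb$category), , drop = FALSE]
    dup <- tb$symbol[duplicated(tb$symbol)]
    setdiff(unique(tb$symbol), dup)
  })
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0L) warning("empty shared gene set")
  sort(shared)
}

#' Gene retention in ancestrally low/high recombining regions
#'
#' For each species and class, counts how many class genes still sit in the
#' corresponding rate categories. Percentages use the two-quartile retained
#' sets (matching the region-classification sets); the all-species
#' intersection uses the strict single extreme quartile. Both set
#' definitions are parameters, and both are reported.
#'
#' @param classGenes list with `ALR` and `AHR` character vectors of symbols
#'   (subsets of the shared set).
#' @param categoryTables named list (per species) of data.frames with
#'   `symbol`, `category`.
#' @param retainedLow,retainedHigh category sets counted as retained for
#'   the percentage (defaults \{Q1,Q2\} / \{Q3,Q4\}).
#' @param strictLow,strictHigh category sets for the all-species
#'   intersection (defaults \{Q1\} / \{Q4\}).
#' @return list with `summary` (data.frame: species, class, retained,
#'   total, percent) and `intersection` (list of symbol vectors per class).
#' @export
retentionSummary <- function(classGenes, categoryTables,
                             retainedLow = c("Q1", "Q2"),
                             retainedHigh = c("Q3", "Q4"),
                             strictLow = "Q1", strictHigh = "Q4") {
  if (any(vapply(classGenes, length, 1L) == 0L))
    stop("empty class gene set")
  rows <- list(); inter <- list()
  for (class in c("ALR", "AHR")) {
    syms <- classGenes[[class]]
    retSet <- if (class == "ALR") retainedLow else retainedHigh
    strSet <- if (class == "ALR") strictLow else strictHigh
    strictKeep <- syms
    for (sp in names(categoryTables)) {
      tb <- categoryTables[[sp]]
      catBySym <- stats::setNames(as.character(tb$category), tb$symbol)
      cats <- catBySym[syms]
      retained <- sum(cats %in% retSet, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, class = class, retained = retained,
        total = length(syms),
        percent = 100 * retained / length(syms))
      strictKeep <- strictKeep[catBySym[strictKeep] %in% strSet]
    }
    inter[[class]] <- sort(strictKeep)
  }
  list(summary = do.call(rbind, rows), intersection = inter)
}
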