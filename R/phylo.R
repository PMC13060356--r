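## Bespoke phylogenomic comparison steps: alignment column filtering and
## subsampling, paired tree comparison, and conservation-score aggregation
## over genomic regions.

DEFAULT_MISSING <- c("-", "N", "?")

## run expr with a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.aln_matrix <- function(aln) {
  if (is(aln, "DNAStringSet") || is(aln, "BStringSet")) {
    if (length(unique(Biostrings::width(aln))) > 1L)
      stop("alignment rows must have equal length")
    m <- as.matrix(aln)
    rownames(m) <- names(aln)
    m
  } else as.matrix(aln)
}

.aln_from_matrix <- function(m) {
  x <- Biostrings::DNAStringSet(apply(m, 1, paste0, collapse = ""))
  names(x) <- rownames(m)
  x
}

#' Filter alignment columns by missingness
#'
#' Removes every alignment column whose fraction of missing symbols is
#' strictly greater than `threshold` (default 0.10): a column at exactly
#' the threshold is retained. Missing symbols are `-`, `N` and `?`,
#' case-insensitive, configurable. Row order is preserved.
#'
#' @param aln a `DNAStringSet` of equal-width aligned sequences (or a
#'   character matrix, taxa in rows).
#' @param threshold maximum tolerated missing fraction, in [0, 1).
#' @param missingSymbols characters treated as missing.
#' @return filtered alignment of the same type as supplied; the surviving
#'   column indices are in `attr(, "kept")`.
#' @export
filterColumnsByMissingness <- function(aln, threshold = 0.10,
                                       missingSymbols = DEFAULT_MISSING) {
  stopifnot(threshold >= 0, threshold < 1)
  m <- .aln_matrix(aln)
  if (ncol(m) == 0L || nrow(m) == 0L) return(aln)
  syms <- unique(c(toupper(missingSymbols), tolower(missingSymbols)))
  missFrac <- colMeans(matrix(m %in% syms, nrow = nrow(m)))
  keep <- which(missFrac <= threshold)
  out <- m[, keep, drop = FALSE]
  res <- if (is(aln, "XStringSet")) .aln_from_matrix(out) else out
  attr(res, "kept") <- keep
  res
}

#' Randomly subsample alignment columns
#'
#' Draws `n` distinct columns uniformly without replacement and emits them
#' in their original genomic order; deterministic for a fixed seed. The
#' default matches the 100,000-column subsample used to keep concatenated
#' region datasets tractable for tree inference.
#'
#' @inheritParams filterColumnsByMissingness
#' @param n number of columns to keep.
#' @param seed integer seed.
#' @return subsampled alignment; chosen column indices in `attr(, "kept")`.
#' @export
subsampleColumns <- function(aln, n = 1e5, seed = 1L) {
  m <- .aln_matrix(aln)
  if (n > ncol(m))
    stop(sprintf("n (%d) exceeds column count (%d)", n, ncol(m)))
  keep <- sort(.with_seed(seed, sample.int(ncol(m), n)))
  out <- m[, keep, drop = FALSE]
  res <- if (is(aln, "XStringSet")) .aln_from_matrix(out) else out
  attr(res, "kept") <- keep
  res
}

.clade_keys <- function(tree) {
  ## for every non-root node, the sorted tip set it subtends
  nt <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  keyOf <- function(node) {
    tips <- if (node <= nt) tree$tip.label[node]
            else tree$tip.label[pp[[node - nt]]]
    paste(sort(tips), collapse = "|")
  }
  nodes <- tree$edge[, 2]
  stats::setNames(vapply(nodes, keyOf, character(1)), nodes)
}

#' Compare branch lengths and node heights of two trees
#'
#' Branches are matched by the clade (taxon set) they subtend after both
#' trees are restricted to their shared taxa; unmatched branches are
#' reported separately. Node heights are root-to-node path lengths,
#' compared for clades present in both topologies. The summary gives the
#' median branch-length ratio B/A and the per-branch differences.
#'
#' @param treeA,treeB rooted `phylo` objects with branch lengths.
#' @return list with `branches` (data.frame: clade, length_A, length_B,
#'   diff, ratio), `unmatched` (per-tree clade keys without a partner),
#'   `heights` (data.frame: clade, height_A, height_B, diff) and `summary`
#'   (median_ratio, n_matched).
#' @export
compareTrees <- function(treeA, treeB) {
  shared <- intersect(treeA$tip.label, treeB$tip.label)
  if (length(shared) < 4L) stop("need >= 4 shared taxa")
  a <- ape::keep.tip(treeA, shared)
  b <- ape::keep.tip(treeB, shared)
  ka <- .clade_keys(a); kb <- .clade_keys(b)
  lenA <- stats::setNames(a$edge.length, ka[as.character(a$edge[, 2])])
  lenB <- stats::setNames(b$edge.length, kb[as.character(b$edge[, 2])])
  common <- intersect(names(lenA), names(lenB))
  if (length(common) == 0L) {
    warning("no shared clades between the two trees")
    return(list(branches = data.frame(), unmatched = list(A = ka, B = kb),
                heights = data.frame(),
                summary = list(median_ratio = NA_real_, n_matched = 0L)))
  }
  branches <- data.frame(clade = common,
                         length_A = unname(lenA[common]),
                         length_B = unname(lenB[common]))
  branches$diff <- branches$length_B - branches$length_A
  branches$ratio <- ifelse(branches$length_A > 0,
                           branches$length_B / branches$length_A, NA_real_)
  hA <- ape::node.depth.edgelength(a)
  hB <- ape::node.depth.edgelength(b)
  nodeA <- stats::setNames(as.integer(names(ka)), ka)
  nodeB <- stats::setNames(as.integer(names(kb)), kb)
  intA <- names(ka)[as.integer(names(ka)) > length(a$tip.label)]
  intB <- names(kb)[as.integer(names(kb)) > length(b$tip.label)]
  hcommon <- intersect(ka[intA], kb[intB])
  heights <- data.frame(clade = hcommon,
                        height_A = hA[nodeA[hcommon]],
                        height_B = hB[nodeB[hcommon]])
  heights$diff <- heights$height_B - heights$height_A
  list(branches = branches,
       unmatched = list(A = setdiff(names(lenA), common),
                        B = setdiff(names(lenB), common)),
       heights = heights,
       summary = list(
         median_ratio = stats::median(branches$ratio, na.rm = TRUE),
         n_matched = nrow(branches)))
}

.weighted_quantile <- function(v, w, probs) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w); tot <- cw[length(cw)]
  vapply(probs, function(q) v[which(cw >= q * tot)[1]], numeric(1))
}

#' Aggregate conservation scores over regions
#'
#' Collects a per-base (or per-interval) score track inside each region and
#' summarises the per-base score distribution; a base is counted once per
#' region containing it. Regions with no data report `n = 0`. If the
#' regions carry a `class` metadata column (e.g. ALR/AHR), pooled
#' per-class distributions are summarised as well. Positive scores
#' conventionally indicate conservation (PhyloP sign convention).
#'
#' @param track `GRanges` with a numeric `score` column; sorted,
#'   non-overlapping.
#' @param regions `GRanges` of regions (optionally with `class`).
#' @return list with `perRegion` and `pooled` data.frames (columns: n,
#'   mean, median, q25, q75).
#' @export
scoresInRegions <- function(track, regions) {
  hits <- findOverlaps(regions, track)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- width(pintersect(granges(regions)[qh], granges(track)[sh]))
  v <- mcols(track)$score[sh]
  summarise <- function(vv, ww) {
    if (length(vv) == 0L)
      return(c(n = 0, mean = NA, median = NA, q25 = NA, q75 = NA))
    q <- .weighted_quantile(vv, ww, c(0.25, 0.5, 0.75))
    c(n = sum(ww), mean = sum(vv * ww) / sum(ww),
      median = q[2], q25 = q[1], q75 = q[3])
  }
  perRegion <- t(vapply(seq_along(regions), function(i) {
    k <- qh == i
    summarise(v[k], w[k])
  }, numeric(5)))
  perRegion <- data.frame(region = seq_along(regions), perRegion)
  names(perRegion) <- c("region", "n", "mean", "median", "q25", "q75")
  pooled <- NULL
  if (!is.null(mcols(regions)$class)) {
    cls <- as.character(mcols(regions)$class)
    pooled <- do.call(rbind, lapply(unique(cls), function(cl) {
      k <- qh %in% which(cls == cl)
      data.frame(class = cl, t(summarise(v[k], w[k])))
    }))
    names(pooled) <- c("class", "n", "mean", "median", "q25", "q75")
  }
  list(perRegion = perRegion, pooled = pooled)
}
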