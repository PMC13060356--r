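## Pathway skew: per-pathway 2x2 contingency counts, Pearson chi-squared
## without continuity correction, and Benjamini-Hochberg adjustment.

#' Read / write GMT gene-set files
#'
#' One gene set per line: name, description, member symbols
#' (tab-separated). Reading is delegated to [fgsea::gmtPathways()].
#'
#' @param path file path.
#' @return named list of character vectors (read); invisible path (write).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  bad <- which(vapply(strsplit(lines, "\t"), length, 1L) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param pathways named list of symbol vectors.
#' @export
writeGmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-pathway 2x2 contingency tables
#'
#' Counts, for each pathway, genes inside/outside the pathway crossed with
#' membership in the ancestrally high versus low recombining gene sets:
#' `a` = in-pathway & high, `b` = in-pathway & low, `c` = out & high,
#' `d` = out & low. Genes in neither class set are ignored; pathways with
#' no classified member (`a + b = 0`) are skipped and logged.
#'
#' @param highSet,lowSet disjoint character vectors of gene symbols.
#' @param pathways named list of symbol vectors (see [readGmt()]).
#' @return data.frame with columns `pathway`, `a`, `b`, `c`, `d`; skipped
#'   pathways in `attr(,"skipped")`.
#' @export
pathwayCounts <- function(highSet, lowSet, pathways) {
  if (length(intersect(highSet, lowSet)))
    stop("highSet and lowSet must be disjoint")
  nH <- length(unique(highSet)); nL <- length(unique(lowSet))
  rows <- lapply(names(pathways), function(nm) {
    p <- unique(pathways[[nm]])
    a <- length(intersect(p, highSet))
    b <- length(intersect(p, lowSet))
    data.frame(pathway = nm, a = a, b = b, c = nH - a, d = nL - b)
  })
  out <- do.call(rbind, rows)
  skipped <- out$pathway[out$a + out$b == 0L]
  out <- out[out$a + out$b > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Pearson chi-squared skew test on a 2x2 table
#'
#' Plain Pearson statistic without continuity correction (df = 1), the
#' documented default here because it is reproducible by hand from
#' expected counts. Direction is `high` when the in-pathway high fraction
#' exceeds the out-of-pathway one, `low` when below, `none` at equality. A
#' table with a zero margin is untestable and flagged.
#'
#' @param a,b,c,d the 2x2 cell counts (see [pathwayCounts()]).
#' @return list with `chi2`, `p`, `direction`, `testable`.
#' @export
skewTest <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(chi2 = NA_real_, p = NA_real_, direction = "none",
                testable = FALSE))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  pin <- a / (a + b); pout <- c / (c + d)
  direction <- if (pin > pout) "high" else if (pin < pout) "low" else "none"
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       direction = direction, testable = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, capped at 1; input order preserved.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pathway skew analysis
#'
#' Runs [pathwayCounts()], [skewTest()] per pathway and [bhAdjust()] across
#' testable pathways; a pathway's direction is reported only when its
#' adjusted p-value falls below `alpha`.
#'
#' @inheritParams pathwayCounts
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame sorted by `p_bh` with columns `pathway`, `a`..`d`,
#'   `ratio` (a/b, `Inf`-safe), `chi2`, `p`, `p_bh`, `direction`.
#' @export
pathwaySkew <- function(highSet, lowSet, pathways, alpha = 0.05) {
  counts <- pathwayCounts(highSet, lowSet, pathways)
  tests <- Map(skewTest, counts$a, counts$b, counts$c, counts$d)
  counts$ratio <- ifelse(counts$b > 0, counts$a / counts$b, Inf)
  counts$chi2 <- vapply(tests, `[[`, numeric(1), "chi2")
  counts$p <- vapply(tests, `[[`, numeric(1), "p")
  counts$direction <- vapply(tests, `[[`, character(1), "direction")
  testable <- vapply(tests, `[[`, logical(1), "testable")
  counts$p_bh <- NA_real_
  counts$p_bh[testable] <- bhAdjust(counts$p[testable])
  counts$direction[!testable | is.na(counts$p_bh) |
                     counts$p_bh >= alpha] <- "none"
  counts[order(counts$p_bh), , drop = FALSE]
}
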