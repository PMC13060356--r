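mkAln <- function(rows) {
  x <- Biostrings::DNAStringSet(rows)
  names(x) <- paste0("t", seq_along(rows))
  x
}

test_that("filterColumnsByMissingness applies the strict >threshold rule", {
  ## 10 taxa: a column with exactly 10% missing is kept, 20% removed
  m <- matrix("A", nrow = 10, ncol = 3)
  m[1, 2] <- "-"           # 10% missing
  m[1:2, 3] <- "N"         # 20% missing
  rownames(m) <- paste0("t", 1:10)
  out <- filterColumnsByMissingness(m, 0.10)
  expect_equal(attr(out, "kept"), c(1, 2))

  ## threshold 0: only complete columns survive
  out0 <- filterColumnsByMissingness(m, 0)
  expect_equal(attr(out0, "kept"), 1L)

  ## missing symbols are case-insensitive and include ?
  m2 <- matrix(c("a", "n", "?", "C"), nrow = 2)
  expect_equal(attr(filterColumnsByMissingness(m2, 0.4), "kept"), integer(0))

  ## DNAStringSet in, DNAStringSet out
  aln <- mkAln(c("AC-T", "ACGT", "ACGT", "ACGT", "ACGT",
                 "ACGT", "ACGT", "ACGT", "ACGT", "ACGT"))
  kept <- filterColumnsByMissingness(aln, 0.10)
  expect_s4_class(kept, "DNAStringSet")
  expect_equal(attr(kept, "kept"), c(1, 2, 3, 4))  # 10% kept
})

test_that("surviving columns equal a brute-force per-column recount", {
  set.seed(61)
  syms <- c("A", "C", "G", "T", "-", "N")
  m <- matrix(sample(syms, 20 * 200, replace = TRUE,
                     prob = c(rep(0.22, 4), 0.06, 0.06)), nrow = 20)
  out <- filterColumnsByMissingness(m, 0.10)
  brute <- which(vapply(seq_len(ncol(m)), function(j)
    mean(m[, j] %in% c("-", "N", "?")) <= 0.10, logical(1)))
  expect_equal(attr(out, "kept"), brute)
})

test_that("subsampleColumns is uniform, ordered and deterministic", {
  m <- matrix(rep(c("A", "C", "G", "T"), each = 5), nrow = 5)
  expect_equal(attr(subsampleColumns(m, 4, seed = 3), "kept"), 1:4)
  s1 <- subsampleColumns(m, 2, seed = 9)
  s2 <- subsampleColumns(m, 2, seed = 9)
  expect_identical(attr(s1, "kept"), attr(s2, "kept"))
  expect_true(!is.unsorted(attr(s1, "kept")))
  expect_error(subsampleColumns(m, 10, seed = 1), "exceeds")

  ## index frequencies over many seeds are near-uniform
  counts <- integer(4)
  for (s in 1:1000) {
    k <- attr(subsampleColumns(m, 2, seed = s), "kept")
    counts[k] <- counts[k] + 1L
  }
  ## each column appears ~500 times; 4-sigma binomial bounds
  expect_true(all(abs(counts - 500) < 4 * sqrt(1000 * 0.5 * 0.5)))
})

test_that("filter then subsample commutes with restricted subsampling", {
  set.seed(71)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 10 * 100, replace = TRUE,
                     prob = c(rep(0.23, 4), 0.08)), nrow = 10)
  filt <- filterColumnsByMissingness(m, 0.10)
  sub <- subsampleColumns(filt, 20, seed = 5)
  ## restricted route: same seed over the surviving column set
  kept <- attr(filt, "kept")
  idx <- sort(ancestralRecomb:::.with_seed(5, sample.int(length(kept), 20)))
  expect_equal(attr(sub, "kept"), idx)
  expect_equal(unname(as.matrix(filt)[, idx]), unname(as.matrix(sub)),
               ignore_attr = TRUE)
})

test_that("compareTrees matches clades, scales and brute-force pairing", {
  t1 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:1):0.5);")
  r <- compareTrees(t1, t1)
  expect_true(all(r$branches$diff == 0))
  expect_equal(r$summary$median_ratio, 1)
  expect_true(all(r$heights$diff == 0))

  t2 <- t1
  t2$edge.length <- t1$edge.length * 2
  r2 <- compareTrees(t1, t2)
  expect_true(all(r2$branches$ratio == 2))
  expect_equal(r2$heights$height_B, 2 * r2$heights$height_A)

  ## random pair: pairing equals brute-force bipartition enumeration
  set.seed(83)
  a <- ape::rtree(8)
  b <- ape::rtree(8)
  r3 <- compareTrees(a, b)
  cladesOf <- function(tr) {
    nt <- length(tr$tip.label)
    vapply(seq_len(nrow(tr$edge)), function(i) {
      node <- tr$edge[i, 2]
      tips <- if (node <= nt) tr$tip.label[node] else
        ape::extract.clade(tr, node)$tip.label
      paste(sort(tips), collapse = "|")
    }, character(1))
  }
  expect_setequal(r3$branches$clade, intersect(cladesOf(a), cladesOf(b)))
  ## per-branch lengths agree with direct edge lookup
  for (i in seq_len(nrow(r3$branches))) {
    cl <- r3$branches$clade[i]
    expect_equal(r3$branches$length_A[i],
                 a$edge.length[which(cladesOf(a) == cl)])
  }

  expect_error(compareTrees(ape::rtree(3), ape::rtree(3)), "4 shared")
})

test_that("scoresInRegions aggregates per-base weighted distributions", {
  track <- GRanges("chr1", IRanges(c(1, 101, 201), width = 100),
                   score = c(1, 2, 3))
  regions <- GRanges("chr1", IRanges(c(1, 151, 1001), c(300, 250, 1100)),
                     class = c("ALR", "AHR", "AHR"))
  r <- scoresInRegions(track, regions)
  expect_equal(r$perRegion$n, c(300, 100, 0))
  expect_equal(r$perRegion$mean[1], 2)            # equal thirds of 1,2,3
  expect_equal(r$perRegion$mean[2], 2.5)          # 50 bases of 2 and of 3
  expect_true(is.na(r$perRegion$mean[3]))         # region outside track

  ## brute-force per-base averaging on a ramp
  baseScore <- rep(c(1, 2, 3), each = 100)
  reg <- GRanges("chr1", IRanges(37, 222))
  rr <- scoresInRegions(track, reg)
  expect_equal(rr$perRegion$mean, mean(baseScore[37:222]))
  expect_equal(rr$perRegion$median,
               as.numeric(stats::quantile(baseScore[37:222], 0.5, type = 1)))

  ## pooled by class
  pooled <- r$pooled
  expect_equal(pooled$n[pooled$class == "AHR"], 100)

  ## constant track: every covered region mean equals the constant
  ctrack <- GRanges("chr1", IRanges(1, 1e4), score = 7)
  rc <- scoresInRegions(ctrack, GRanges("chr1", IRanges(c(5, 500),
                                                        c(50, 900))))
  expect_true(all(rc$perRegion$mean == 7))
})

test_that("toy alignment pairs reflect the rate multiplier", {
  tree <- ape::read.tree(text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  pair <- simulateAlignmentPair(tree, 2000, rateMultiplier = 1,
                                missingFraction = 0, seed = 2)
  ## no missing symbols when missingFraction = 0
  expect_false(any(grepl("N", as.character(pair$alnA))))
  ## equal-rate datasets: pairwise mismatch fractions agree within noise
  mm <- function(aln) {
    m <- as.matrix(aln)
    mean(m["a", ] != m["b", ])
  }
  expect_lt(abs(mm(pair$alnA) - mm(pair$alnB)), 0.04)

  ## doubling the rate raises divergence
  pair2 <- simulateAlignmentPair(tree, 2000, rateMultiplier = 3, seed = 2)
  expect_gt(mm(pair2$alnB), mm(pair2$alnA) + 0.02)

  ## missingness injected at the requested fraction
  pair3 <- simulateAlignmentPair(tree, 1000, missingFraction = 0.2, seed = 4)
  frac <- mean(as.matrix(pair3$alnA) == "N")
  expect_gt(frac, 0.15); expect_lt(frac, 0.25)

  expect_error(simulateAlignmentPair(tree, 0), "nColumns")
  expect_error(simulateAlignmentPair("((a:1,b", 10), "malformed")
  expect_error(simulateAlignmentPair(tree, 10, rateMultiplier = 0), "> 0")
})
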