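test_that("identical configs give byte-identical simulations", {
  cfg <- tinyConfig(seed = 3)
  s1 <- suppressWarnings(simulateStudy(cfg))
  s2 <- suppressWarnings(simulateStudy(cfg))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- suppressWarnings(simulateStudy(tinyConfig(seed = 4)))
  expect_false(identical(
    syntenyBlocks(s1$karyo$species$sp2$toAncestor),
    syntenyBlocks(s3$karyo$species$sp2$toAncestor)))
})

test_that("zero rearrangements leave species identical to the ancestor", {
  cfg <- tinyConfig(nFissions = 0, nFusions = 0, nInversions = 0)
  karyo <- simulateKaryotypes(cfg)
  for (sp in names(karyo$species)) {
    b <- syntenyBlocks(karyo$species[[sp]]$toAncestor)
    expect_true(all(b$strand == "+"))
    expect_equal(b$src_start, b$dst_start)
    expect_equal(b$src_end, b$dst_end)
    expect_equal(sort(unname(karyo$species[[sp]]$chromSizes)),
                 sort(unname(cfg$ancestralChromosomes)))
  }
})

test_that("a single fission yields two complementary chromosomes", {
  cfg <- simConfig(seed = 5,
                   ancestralChromosomes = c(A1 = 1e8, A2 = 3e7),
                   nFissions = 1, nFusions = 0, nInversions = 0,
                   nPlantedCold = 0, nPlantedHot = 0)
  karyo <- simulateKaryotypes(cfg)
  sp <- karyo$species$sp2
  expect_length(sp$chromSizes, 3)
  expect_equal(sum(sp$chromSizes), 1.3e8)
  b <- syntenyBlocks(sp$toAncestor)
  ## blocks tile the species genome exactly once
  expect_equal(sum(b$src_end - b$src_start), 1.3e8)
  for (cn in names(sp$chromSizes)) {
    bb <- b[b$src_chrom == cn, ]
    bb <- bb[order(bb$src_start), ]
    expect_equal(bb$src_start[1], 0)
    expect_equal(bb$src_end[nrow(bb)], unname(sp$chromSizes[cn]))
    if (nrow(bb) > 1)
      expect_equal(bb$src_start[-1], bb$src_end[-nrow(bb)])
  }
  ## the two fission products partition one ancestral chromosome
  fis <- karyo$rearrangements[karyo$rearrangements$op == "fission" &
                              karyo$rearrangements$species == "sp2", ]
  expect_equal(nrow(fis), 1)
})

test_that("rearrangement counts beyond chromosome capacity are rejected", {
  expect_error(simConfig(ancestralChromosomes = c(A = 1e7, B = 1e7),
                         nFissions = 0, nFusions = 3,
                         nPlantedCold = 0, nPlantedHot = 0),
               "fusions impossible")
  ## planted chains occupy all long chromosomes: nothing left to rearrange
  cfg <- simConfig(seed = 1,
                   ancestralChromosomes = c(A1 = 3e7),
                   shortChromThreshold = 1e7,
                   nPlantedCold = 2, nPlantedHot = 2,
                   nFissions = 1, nFusions = 0, nInversions = 0)
  expect_error(simulateKaryotypes(cfg), "planted-free")
})

test_that("species-ancestor projections compose through the reference", {
  cfg <- tinyConfig(seed = 13)
  karyo <- suppressWarnings(simulateKaryotypes(cfg))
  ref <- karyo$reference
  refToAnc <- karyo$species[[ref]]$toAncestor
  set.seed(77)
  for (sp in setdiff(names(karyo$species), ref)) {
    spToAnc <- syntenyBlocks(karyo$species[[sp]]$toAncestor)
    spToRef <- invertSyntenyMap(karyo$species[[sp]]$fromReference)
    i <- sample(nrow(spToAnc), 250, replace = TRUE)
    p <- spToAnc$src_start[i] + vapply(
      spToAnc$src_end[i] - spToAnc$src_start[i],
      function(w) sample.int(w, 1), numeric(1)) - 1
    direct <- vapply(seq_along(i), function(k)
      projectCoordinate(spToAnc[i[k], ], p[k]), numeric(1))
    pts <- GRanges(spToAnc$src_chrom[i], IRanges(p + 1, p + 1))
    viaRef <- projectRegions(pts, spToRef)$mapped
    viaAnc <- projectRegions(viaRef, refToAnc)$mapped
    ## compose indices back to the original points
    ptIdx <- mcols(viaRef)$region[mcols(viaAnc)$region]
    agree <- abs(start(viaAnc) - 1 - direct[ptIdx]) <= 2 &
      as.character(seqnames(viaAnc)) == spToAnc$dst_chrom[i][ptIdx]
    expect_gt(mean(agree), 0.99)
    expect_gt(length(agree), 200)
  }
})

test_that("planted regions project onto the recorded per-species intervals", {
  cfg <- tinyConfig(seed = 19)
  karyo <- suppressWarnings(simulateKaryotypes(cfg))
  planted <- karyo$planted
  expect_true(all(planted$end - planted$start >= 2 * cfg$windowSize))
  ## non-overlapping on the ancestor
  pg <- GRanges(planted$chrom, IRanges(planted$start + 1, planted$end))
  expect_equal(length(GenomicRanges::reduce(pg)), length(pg))
  for (sp in names(karyo$species)) {
    m <- karyo$groundTruth$perSpecies[[sp]]
    ## every planted region is represented and lengths are preserved
    lens <- tapply(width(m), mcols(m)$region, sum)
    expect_equal(sort(as.integer(names(lens))), seq_len(nrow(planted)))
    expect_true(all(abs(lens - (planted$end - planted$start)) <= 2))
  }
})

test_that("landscape degenerates to a constant without boost and noise", {
  cfg <- tinyConfig(telomereBoost = 0, noiseSd = 0,
                    nPlantedCold = 0, nPlantedHot = 0,
                    nFissions = 0, nFusions = 0, nInversions = 0)
  karyo <- simulateKaryotypes(cfg)
  maps <- simulateRecombinationLandscape(karyo, cfg)
  for (m in maps)
    expect_true(all(mcols(rateWindows(m))$rate == 1))
})

test_that("planted tiles sit in the rate extremes and separate cleanly", {
  cfg <- tinyConfig(seed = 29, noiseSd = 0)
  karyo <- suppressWarnings(simulateKaryotypes(cfg))
  maps <- simulateRecombinationLandscape(karyo, cfg)
  truth <- karyo$groundTruth$perSpecies
  for (sp in names(maps)) {
    w <- rateWindows(maps[[sp]])
    r <- mcols(w)$rate
    m <- truth[[sp]]
    inCold <- overlapsAny(w, m[mcols(m)$class == "ALR"], type = "within")
    inHot <- overlapsAny(w, m[mcols(m)$class == "AHR"], type = "within")
    ## every cold tile ranks strictly below every hot tile
    expect_lt(max(r[inCold]), min(r[inHot]))
    ## cold tiles in the bottom quartile of the genome-wide ranking
    expect_true(all(r[inCold] <= stats::quantile(r, 0.25)))
    expect_true(all(r[inHot] >= stats::quantile(r, 0.75)))
  }
})

test_that("short chromosomes are uniformly elevated", {
  cfg <- tinyConfig(seed = 37, nPlantedCold = 0, nPlantedHot = 0,
                    nFissions = 0, nFusions = 0, nInversions = 0,
                    noiseSd = 0.05)
  karyo <- simulateKaryotypes(cfg)
  maps <- simulateRecombinationLandscape(karyo, cfg)
  w <- rateWindows(maps$sp1)
  r <- mcols(w)$rate
  short <- as.character(seqnames(w)) == "sp1_chr3"  # the 8 Mb chromosome
  expect_true(all(r[short] >= stats::median(r)))
})

test_that("genes and pathways respect the planted composition", {
  cfg <- tinyConfig(seed = 43, locFraction = 0,
                    pathwaySpec = list(
                      list(name = "allhot", n = 10, plantedHighFraction = 1),
                      list(name = "half", n = 20, plantedHighFraction = 0.5)))
  karyo <- suppressWarnings(simulateKaryotypes(cfg))
  g <- simulateGenesAndPathways(karyo, cfg)
  expect_true(all(g$pathways$allhot %in% g$hotResidents))
  expect_equal(sum(g$pathways$half %in% g$hotResidents), 10)
  ## locFraction 0: no LOC symbols anywhere
  expect_false(any(grepl("^LOC", g$orthogroups$symbol)))
  ## one-to-one orthologs: every gene appears once per covered species
  expect_true(all(table(g$orthogroups$orthogroup,
                        g$orthogroups$species) <= 1))

  cfgLoc <- tinyConfig(seed = 43, locFraction = 0.3)
  gl <- simulateGenesAndPathways(karyo, cfgLoc)
  expect_gt(sum(grepl("^LOC", gl$orthogroups$symbol)), 0)

  ## impossible pathway demands are rejected
  cfgBad <- tinyConfig(seed = 43, geneCount = 50,
                       pathwaySpec = list(list(name = "x", n = 40,
                                               plantedHighFraction = 1)))
  karyoBad <- suppressWarnings(simulateKaryotypes(cfgBad))
  expect_error(simulateGenesAndPathways(karyoBad, cfgBad), "planted-hot")
})

test_that("planted-high gene placement follows binomial expectation", {
  hits <- vapply(1:10, function(s) {
    cfg <- tinyConfig(seed = s, pathwaySpec = list(
      list(name = "half", n = 20, plantedHighFraction = 0.5)))
    karyo <- suppressWarnings(simulateKaryotypes(cfg))
    g <- simulateGenesAndPathways(karyo, cfg)
    sum(g$pathways$half %in% g$hotResidents)
  }, numeric(1))
  ## exactly round(n * fraction) planted members by construction
  expect_true(all(hits == 10))
})
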