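## Multi-species simulator with planted ground truth: ancestral karyotype,
## rearranged species genomes with synteny, recombination landscapes with
## planted conserved hot/cold regions, genes/pathways, and toy alignments.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe four ~200 Mb genomes derived from a five-chromosome
#' ancestor (one short chromosome), each species carrying one fission, one
#' fusion and two inversions, with 15 planted ancestrally-cold and 15
#' ancestrally-hot regions of two 1.5 Mb windows each.
#'
#' @param seed integer master seed; a fixed seed gives byte-identical
#'   output.
#' @param nSpecies number of extant species (the first is the reference).
#' @param ancestralChromosomes named numeric vector of ancestral
#'   chromosome lengths (bp).
#' @param nFissions,nFusions,nInversions rearrangements applied per
#'   species.
#' @param telomereBoost unitless multiplier >= 0 for the telomeric rate
#'   elevation.
#' @param shortChromThreshold chromosomes below this length (bp) get a
#'   uniformly elevated rate.
#' @param nPlantedCold,nPlantedHot numbers of planted conserved regions.
#' @param plantedRegionLength planted region length (bp); must be at least
#'   two analysis windows.
#' @param noiseSd sd of the per-tile log-normal rate noise (log scale).
#' @param geneCount number of simulated orthologous genes.
#' @param locFraction fraction of per-species gene symbols replaced by LOC
#'   placeholders.
#' @param pathwaySpec list of `list(name=, n=, plantedHighFraction=)`
#'   entries describing simulated pathways.
#' @param tile raw rate-track resolution (bp).
#' @param windowSize downstream analysis window (bp).
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L, nSpecies = 4L,
                      ancestralChromosomes = c(ANC1 = 60e6, ANC2 = 55e6,
                                               ANC3 = 45e6, ANC4 = 35e6,
                                               ANC5 = 15e6),
                      nFissions = 1L, nFusions = 1L, nInversions = 2L,
                      telomereBoost = 1, shortChromThreshold = 2e7,
                      nPlantedCold = 15L, nPlantedHot = 15L,
                      plantedRegionLength = 3e6, noiseSd = 0.2,
                      geneCount = 1000L, locFraction = 0.1,
                      pathwaySpec = list(), tile = 5e4,
                      windowSize = 1.5e6) {
  cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
              ancestralChromosomes = ancestralChromosomes,
              nFissions = nFissions, nFusions = nFusions,
              nInversions = nInversions, telomereBoost = telomereBoost,
              shortChromThreshold = shortChromThreshold,
              nPlantedCold = nPlantedCold, nPlantedHot = nPlantedHot,
              plantedRegionLength = plantedRegionLength, noiseSd = noiseSd,
              geneCount = geneCount, locFraction = locFraction,
              pathwaySpec = pathwaySpec, tile = tile,
              windowSize = windowSize)
  if (any(ancestralChromosomes <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(names(ancestralChromosomes)))
    stop("ancestral chromosomes must be named")
  if (telomereBoost < 0) stop("telomereBoost must be >= 0")
  if (plantedRegionLength < 2 * windowSize)
    stop("planted regions must span at least 2 windows")
  if (noiseSd < 0 || locFraction < 0 || locFraction > 1)
    stop("invalid noiseSd or locFraction")
  nchr <- length(ancestralChromosomes)
  if (nFusions > nchr + nFissions - 1)
    stop(sprintf(paste("%d fusions impossible: only %d chromosomes after",
                       "%d fissions"), nFusions, nchr + nFissions,
                 nFissions))
  class(cfg) <- "SimConfig"
  cfg
}

## deterministic U-shaped base rate on the ancestral karyotype:
## 1 + boost * exp(-dist_to_end / (L/10)) on long chromosomes, constant
## 1 + boost on short ones
.base_rate <- function(chrom, pos, cfg) {
  L <- cfg$ancestralChromosomes[chrom]
  ifelse(L < cfg$shortChromThreshold, 1 + cfg$telomereBoost,
         1 + cfg$telomereBoost * exp(-pmin(pos, L - pos) / (L / 10)))
}

#' Place planted conserved regions on the ancestral karyotype
#'
#' Planted regions live on the ancestor and are propagated to every species
#' through the rearrangements, so cross-species conservation holds by
#' construction. Regions are laid out as alternating cold/hot chains along
#' long ancestral chromosomes, anchored at chromosome tips and separated by
#' single transition windows — mirroring how ancestrally low and high
#' recombining loci interleave along real chromosomes, and giving every
#' planted region an opposite-class neighbour (or a chromosome end) on both
#' sides so that its rate contrast is locally detectable. A chain that
#' stops mid-chromosome ends with a hot region, whose high-rate run is
#' terminated by the low mid-chromosome background of the U-shaped base
#' landscape. `plantedRegionLength` is the nominal (minimum) region length;
#' chain-end regions may be extended by up to two windows to reach the
#' chromosome tip.
#'
#' @param config a [simConfig()].
#' @return data.frame with `class` ("cold"/"hot"), `chrom`, `start`, `end`
#'   (0-based half-open, ancestor coordinates).
#' @export
plantRegions <- function(config) {
  cfg <- config
  win <- cfg$windowSize
  k <- round(cfg$plantedRegionLength / win)  # windows per region (>= 2)
  long <- cfg$ancestralChromosomes[
    cfg$ancestralChromosomes >= cfg$shortChromThreshold]
  long <- sort(long, decreasing = TRUE)
  needC <- cfg$nPlantedCold
  needH <- cfg$nPlantedHot
  if (needC + needH == 0L)
    return(data.frame(class = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  capTotal <- sum(vapply(long, function(L)
    floor((floor(L / win) + 1) / (k + 1)), numeric(1)))
  if (capTotal < needC + needH)
    stop(sprintf(paste("cannot place %d planted regions: chromosome",
                       "capacity is %d regions of %d windows"),
                 needC + needH, capTotal, k))
  rows <- list()
  for (chr in names(long)) {
    if (needC + needH == 0L) break
    W <- floor(long[[chr]] / win)
    nCap <- floor((W + 1) / (k + 1))
    m <- min(nCap, needC + needH)
    if (m == 0L) next
    ## alternate classes, starting with whichever class needs more
    start <- if (needC >= needH) "cold" else "hot"
    classes <- rep(c(start, setdiff(c("cold", "hot"), start)),
                   length.out = m)
    ## cap by per-class need, then enforce a hot inner end on partial
    ## chains (a trailing cold region would bleed into the low-rate
    ## mid-chromosome background)
    keep <- cumsum(classes == "cold") <= needC &
      cumsum(classes == "hot") <= needH
    classes <- classes[keep]
    m <- length(classes)
    if (m == 0L) next
    partial <- m < nCap
    if (partial && classes[m] == "cold") {
      classes <- classes[-m]
      m <- m - 1L
      if (m == 0L) next
    }
    starts <- (seq_len(m) - 1L) * (k + 1L) * win
    ends <- starts + k * win
    if (!partial) {
      ## extend the last region(s) toward the tip (up to +2 windows each)
      extra <- W - ((k + 1L) * m - 1L)
      add <- min(extra, 2L)
      ends[m] <- ends[m] + add * win
    }
    rows[[chr]] <- data.frame(class = classes, chrom = chr,
                              start = starts, end = ends,
                              stringsAsFactors = FALSE)
    needC <- needC - sum(classes == "cold")
    needH <- needH - sum(classes == "hot")
  }
  if (needC + needH > 0L)
    stop(sprintf(paste("could not place all planted regions (%d cold, %d",
                       "hot unplaced): chain layout requires partial",
                       "chains to end hot"), needC, needH))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- karyotype rearrangement machinery --------------------------------
## a species genome is a list of chromosomes; each chromosome a data.frame
## of blocks (anc_chrom, anc_start, anc_end, strand) in species order

.blocks_len <- function(df) sum(df$anc_end - df$anc_start)

## split one chromosome's block list at species-coordinate pos
.split_at <- function(df, pos) {
  w <- df$anc_end - df$anc_start
  cum <- cumsum(w)
  tot <- cum[length(cum)]
  stopifnot(pos > 0, pos < tot)
  i <- which(cum >= pos)[1]
  before <- if (i > 1) cum[i - 1] else 0
  off <- pos - before
  if (off == w[i]) {
    list(df[seq_len(i), , drop = FALSE],
         df[-seq_len(i), , drop = FALSE])
  } else {
    b <- df[i, ]
    if (b$strand == "+") {
      left <- transform(b, anc_end = anc_start + off)
      right <- transform(b, anc_start = anc_start + off)
    } else {
      left <- transform(b, anc_start = anc_end - off)
      right <- transform(b, anc_end = anc_end - off)
    }
    list(rbind(df[seq_len(i - 1), , drop = FALSE], left),
         rbind(right, df[-seq_len(i), , drop = FALSE]))
  }
}

.invert_segment <- function(df, s, e) {
  p1 <- .split_at(df, s)
  p2 <- .split_at(p1[[2]], e - s)
  mid <- p2[[1]][rev(seq_len(nrow(p2[[1]]))), , drop = FALSE]
  mid$strand <- ifelse(mid$strand == "+", "-", "+")
  rbind(p1[[1]], mid, p2[[2]])
}

## map a species coordinate to its ancestral position
.anc_pos <- function(df, pos) {
  w <- df$anc_end - df$anc_start
  cum <- cumsum(w)
  i <- which(cum > pos)[1]
  before <- if (i > 1) cum[i - 1] else 0
  off <- pos - before
  if (df$strand[i] == "+") df$anc_start[i] + off else df$anc_end[i] - off
}

## sample a breakpoint avoiding planted regions (+/- buffer) when possible
.sample_breakpoint <- function(df, planted, buffer = 5e5) {
  tot <- .blocks_len(df)
  for (try in 1:200) {
    pos <- sample.int(tot - 1L, 1L)
    if (nrow(planted) == 0L) return(list(pos = pos, split = FALSE))
    ap <- .anc_pos(df, pos)
    achr <- {
      w <- df$anc_end - df$anc_start
      i <- which(cumsum(w) > pos)[1]
      df$anc_chrom[i]
    }
    hit <- planted$chrom == achr & ap > planted$start - buffer &
      ap < planted$end + buffer
    if (!any(hit)) return(list(pos = pos, split = FALSE))
  }
  warning("breakpoint falls inside a planted region; recorded as split")
  list(pos = pos, split = TRUE)
}

## chromosomes carrying no planted material are eligible for rearrangement;
## conserved regions are identified on karyotypically stable chromosomes,
## so simulated rearrangements are confined to the unstable remainder
.eligible_chroms <- function(chroms, plantedChroms, minLen = 0) {
  ok <- vapply(chroms, function(df)
    !any(df$anc_chrom %in% plantedChroms) && .blocks_len(df) > minLen,
    logical(1))
  which(ok)
}

#' Simulate rearranged species karyotypes with synteny
#'
#' Starting from the ancestral karyotype, each species receives the
#' configured numbers of fissions, fusions and inversions (in that order),
#' with breakpoints sampled uniformly but avoiding planted regions where
#' possible (a breakpoint inside a planted region triggers a warning and is
#' recorded as a split). Synteny block tables are emitted per species
#' against both the ancestor and the reference species (the first species),
#' tiling every species genome exactly once.
#'
#' @param config a [simConfig()].
#' @param planted planted-region table from [plantRegions()]; `NULL`
#'   computes it from `config`.
#' @return list with `species` (per-species: `chromSizes`, `toAncestor`
#'   [SyntenyMap-class], `fromReference`), `reference`, `planted`,
#'   `groundTruth` (planted calls with per-species intervals) and
#'   `rearrangements` (log data.frame).
#' @export
simulateKaryotypes <- function(config, planted = NULL) {
  cfg <- config
  if (is.null(planted)) planted <- plantRegions(cfg)
  spNames <- sprintf("sp%d", seq_len(cfg$nSpecies))
  rlog <- list()
  species <- .with_seed(cfg$seed + 202L, lapply(spNames, function(sp) {
    chroms <- lapply(names(cfg$ancestralChromosomes), function(chr)
      data.frame(anc_chrom = chr, anc_start = 0,
                 anc_end = cfg$ancestralChromosomes[[chr]], strand = "+",
                 stringsAsFactors = FALSE))
    plantedChroms <- unique(planted$chrom)
    for (k in seq_len(cfg$nFissions)) {
      ok <- .eligible_chroms(chroms, plantedChroms, minLen = 2)
      if (!length(ok))
        stop("no rearrangeable (planted-free) chromosome left for fission")
      i <- ok[sample.int(length(ok), 1L)]
      bp <- .sample_breakpoint(chroms[[i]], planted)
      halves <- .split_at(chroms[[i]], bp$pos)
      chroms[[i]] <- halves[[1]]
      chroms[[length(chroms) + 1L]] <- halves[[2]]
      rlog[[length(rlog) + 1L]] <<- data.frame(species = sp, op = "fission",
        detail = sprintf("chrom %d at %d%s", i, bp$pos,
                         if (bp$split) " (splits planted region)" else ""))
    }
    for (k in seq_len(cfg$nFusions)) {
      ok <- .eligible_chroms(chroms, plantedChroms)
      if (length(ok) < 2L)
        stop("need two rearrangeable (planted-free) chromosomes to fuse")
      ij <- ok[sample.int(length(ok), 2L)]
      chroms[[ij[1]]] <- rbind(chroms[[ij[1]]], chroms[[ij[2]]])
      chroms[[ij[2]]] <- NULL
      rlog[[length(rlog) + 1L]] <<- data.frame(species = sp, op = "fusion",
        detail = sprintf("chroms %d+%d", ij[1], ij[2]))
    }
    for (k in seq_len(cfg$nInversions)) {
      ok <- .eligible_chroms(chroms, plantedChroms, minLen = 4e6)
      if (!length(ok))
        stop("no rearrangeable (planted-free) chromosome for inversion")
      i <- ok[sample.int(length(ok), 1L)]
      tot <- .blocks_len(chroms[[i]])
      b1 <- .sample_breakpoint(chroms[[i]], planted)
      b2 <- .sample_breakpoint(chroms[[i]], planted)
      s <- min(b1$pos, b2$pos); e <- max(b1$pos, b2$pos)
      if (e > s) {
        chroms[[i]] <- .invert_segment(chroms[[i]], s, e)
        rlog[[length(rlog) + 1L]] <<- data.frame(species = sp,
          op = "inversion",
          detail = sprintf("chrom %d [%d,%d) of %d", i, s, e, tot))
      }
    }
    ## name chromosomes by decreasing length, species-prefixed
    lens <- vapply(chroms, .blocks_len, 1)
    chroms <- chroms[order(-lens)]
    names(chroms) <- sprintf("%s_chr%d", sp, seq_along(chroms))
    chroms
  }))
  names(species) <- spNames
  out <- lapply(spNames, function(sp) {
    chroms <- species[[sp]]
    blocks <- do.call(rbind, lapply(names(chroms), function(cn) {
      df <- chroms[[cn]]
      w <- df$anc_end - df$anc_start
      cum <- cumsum(w)
      data.frame(src_chrom = cn, src_start = c(0, cum[-length(cum)]),
                 src_end = cum, dst_chrom = df$anc_chrom,
                 dst_start = df$anc_start, dst_end = df$anc_end,
                 strand = df$strand, stringsAsFactors = FALSE)
    }))
    sizes <- vapply(chroms, .blocks_len, 1)
    list(chromSizes = sizes,
         toAncestor = SyntenyMap(sp, "ancestor", blocks))
  })
  names(out) <- spNames
  reference <- spNames[1]
  ## fromReference maps reference -> species: compose ref->anc, anc->sp
  refToAnc <- out[[reference]]$toAncestor
  for (sp in setdiff(spNames, reference))
    out[[sp]]$fromReference <- composeSyntenyMaps(
      refToAnc, invertSyntenyMap(out[[sp]]$toAncestor))
  plantedGr <- GRanges(planted$chrom,
                       IRanges(planted$start + 1, planted$end),
                       class = ifelse(planted$class == "cold",
                                      "ALR", "AHR"))
  perSpecies <- lapply(spNames, function(sp) {
    ancToSp <- invertSyntenyMap(out[[sp]]$toAncestor)
    m <- projectRegions(plantedGr, ancToSp)$mapped
    mcols(m)$class <- mcols(plantedGr)$class[mcols(m)$region]
    m
  })
  names(perSpecies) <- spNames
  list(species = out, reference = reference, planted = planted,
       groundTruth = list(plantedCalls = plantedGr,
                          perSpecies = perSpecies),
       rearrangements = if (length(rlog)) do.call(rbind, rlog) else
         data.frame(species = character(0), op = character(0),
                    detail = character(0)))
}

#' Simulate per-species recombination landscapes
#'
#' The deterministic base landscape lives on the ancestral karyotype —
#' U-shaped along long chromosomes (multiplicative telomere-proximity boost
#' decaying with scale L/10) and uniformly elevated on chromosomes below
#' the short-chromosome threshold — and each species inherits it through
#' its synteny, which is the conservation premise the downstream caller is
#' meant to detect. Per-tile multiplicative log-normal noise is then
#' applied independently per species, and planted cold/hot tiles are drawn
#' from the bottom/top decile of that species' rate distribution.
#'
#' @param karyo result of [simulateKaryotypes()].
#' @param config the same [simConfig()].
#' @return named list of raw per-species [RecombMap-class] tracks at tile
#'   resolution.
#' @export
simulateRecombinationLandscape <- function(karyo, config) {
  cfg <- config
  planted <- karyo$planted
  maps <- .with_seed(cfg$seed + 303L,
    lapply(names(karyo$species), function(sp) {
      blocks <- syntenyBlocks(karyo$species[[sp]]$toAncestor)
      sizes <- karyo$species[[sp]]$chromSizes
      grl <- lapply(names(sizes), function(cn) {
        L <- sizes[[cn]]
        starts <- seq(0, L - 1, by = cfg$tile)
        ends <- pmin(starts + cfg$tile, L)
        mids <- (starts + ends) / 2
        ancChrom <- rep(NA_character_, length(mids))
        ancPos <- rep(NA_real_, length(mids))
        bb <- blocks[blocks$src_chrom == cn, , drop = FALSE]
        for (i in seq_len(nrow(bb))) {
          sel <- mids >= bb$src_start[i] & mids < bb$src_end[i]
          frac <- (mids[sel] - bb$src_start[i]) /
            (bb$src_end[i] - bb$src_start[i])
          ancPos[sel] <- if (bb$strand[i] == "+")
            bb$dst_start[i] + frac * (bb$dst_end[i] - bb$dst_start[i])
          else bb$dst_end[i] - frac * (bb$dst_end[i] - bb$dst_start[i])
          ancChrom[sel] <- bb$dst_chrom[i]
        }
        base <- .base_rate(ancChrom, ancPos, cfg)
        rate <- base * exp(stats::rnorm(length(base), 0, cfg$noiseSd))
        data.frame(chrom = cn, start = starts + 1, end = ends,
                   rate = rate, anc_chrom = ancChrom, anc_pos = ancPos,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, grl)
      tiles <- GRanges(df$chrom, IRanges(df$start, df$end),
                       rate = df$rate, anc_chrom = df$anc_chrom,
                       anc_pos = df$anc_pos)
      r <- mcols(tiles)$rate
      q10 <- stats::quantile(r, 0.10)
      q90 <- stats::quantile(r, 0.90)
      for (j in seq_len(nrow(planted))) {
        sel <- which(mcols(tiles)$anc_chrom == planted$chrom[j] &
                     mcols(tiles)$anc_pos >= planted$start[j] &
                     mcols(tiles)$anc_pos < planted$end[j])
        if (!length(sel)) next
        r[sel] <- if (planted$class[j] == "cold")
          stats::runif(length(sel), 0.3, 0.9) * q10
        else stats::runif(length(sel), 1.1, 1.7) * q90
      }
      mcols(tiles)$rate <- r
      mcols(tiles)$anc_chrom <- NULL
      mcols(tiles)$anc_pos <- NULL
      RecombMap(sp, tiles, "simulated raw tile track")
    }))
  names(maps) <- names(karyo$species)
  maps
}

#' Simulate genes, orthogroups and pathways
#'
#' Orthologous single-copy genes are placed uniformly on the ancestral
#' karyotype and projected into every species. Pathways draw the requested
#' fraction of their members from genes resident in planted hot regions
#' (the rest from genes outside all planted regions), and a configurable
#' fraction of per-species symbols is replaced by LOC placeholders to
#' exercise symbol resolution.
#'
#' @param karyo result of [simulateKaryotypes()].
#' @param config the same [simConfig()].
#' @param geneLength simulated gene span (bp).
#' @return list with `ancestralGenes` (GRanges), `speciesGenes` (named list
#'   of GRanges with `symbol`), `orthogroups` (long data.frame),
#'   `pathways` (named list of symbol vectors) and membership vectors
#'   `hotResidents` / `coldResidents`.
#' @export
simulateGenesAndPathways <- function(karyo, config, geneLength = 1e4) {
  cfg <- config
  planted <- karyo$planted
  .with_seed(cfg$seed + 404L, {
    lens <- cfg$ancestralChromosomes
    chrom <- sample(names(lens), cfg$geneCount, replace = TRUE,
                    prob = lens / sum(lens))
    start <- floor(stats::runif(cfg$geneCount) *
                     (lens[chrom] - geneLength))
    genes <- GRanges(chrom, IRanges(start + 1, start + geneLength),
                     symbol = sprintf("GENE%04d", seq_len(cfg$geneCount)))
    genes <- genes[order(as.character(seqnames(genes)), start(genes))]
    plantedGr <- GRanges(planted$chrom,
                         IRanges(planted$start + 1, planted$end),
                         class = planted$class)
    mid <- GRanges(seqnames(genes),
                   IRanges(floor((start(genes) + end(genes)) / 2), width = 1))
    inHot <- overlapsAny(mid, plantedGr[mcols(plantedGr)$class == "hot"])
    inCold <- overlapsAny(mid, plantedGr[mcols(plantedGr)$class == "cold"])
    hotResidents <- mcols(genes)$symbol[inHot]
    coldResidents <- mcols(genes)$symbol[inCold]
    outside <- mcols(genes)$symbol[!inHot & !inCold]
    pathways <- list()
    for (psp in cfg$pathwaySpec) {
      nHot <- round(psp$n * psp$plantedHighFraction)
      if (nHot > length(hotResidents))
        stop(sprintf("pathway '%s' needs %d planted-hot genes; only %d lie
 in planted hot regions", psp$name, nHot, length(hotResidents)))
      if (psp$n - nHot > length(outside))
        stop(sprintf("pathway '%s' exceeds available background genes",
                     psp$name))
      pathways[[psp$name]] <- c(sample(hotResidents, nHot),
                                sample(outside, psp$n - nHot))
    }
    ## per-species projections and LOC placeholders
    locCounter <- 0L
    orthoRows <- list()
    speciesGenes <- lapply(names(karyo$species), function(sp) {
      ancToSp <- invertSyntenyMap(karyo$species[[sp]]$toAncestor)
      proj <- projectRegions(genes, ancToSp)
      m <- proj$mapped
      ## one interval per gene: keep the longest mapped piece
      keep <- unlist(lapply(split(seq_along(m), mcols(m)$region),
                            function(ix) ix[which.max(width(m)[ix])]))
      m <- m[keep]
      symbols <- mcols(genes)$symbol[mcols(m)$region]
      nLoc <- stats::rbinom(1L, length(symbols), cfg$locFraction)
      locIdx <- sample(seq_along(symbols), nLoc)
      shown <- symbols
      if (nLoc > 0) {
        shown[locIdx] <- sprintf("LOC%d", locCounter + seq_len(nLoc))
        locCounter <<- locCounter + nLoc
      }
      orthoRows[[sp]] <<- data.frame(
        orthogroup = sprintf("OG%04d", mcols(m)$region),
        species = sp, symbol = shown, stringsAsFactors = FALSE)
      out <- granges(m)
      mcols(out)$symbol <- shown
      mcols(out)$true_symbol <- symbols
      out
    })
    names(speciesGenes) <- names(karyo$species)
    list(ancestralGenes = genes, speciesGenes = speciesGenes,
         orthogroups = do.call(rbind, unname(orthoRows)),
         pathways = pathways, hotResidents = hotResidents,
         coldResidents = coldResidents, outside = outside)
  })
}

#' Simulate a pair of alignments under contrasting substitution rates
#'
#' Sites evolve independently under an equal-rates four-state substitution
#' process along the supplied tree; dataset B uses the same tree with every
#' branch length multiplied by `rateMultiplier`. Missing data (`N`) is
#' injected per cell at the stated fraction.
#'
#' @param tree a rooted `phylo` object with branch lengths, or a newick
#'   string.
#' @param nColumns number of alignment columns (> 0).
#' @param rateMultiplier branch-length scale factor for dataset B (> 0).
#' @param missingFraction probability a cell is masked, in [0, 1).
#' @param seed integer seed.
#' @return list with `alnA`, `alnB` (`DNAStringSet`) and `tree`.
#' @export
simulateAlignmentPair <- function(tree, nColumns, rateMultiplier = 1,
                                  missingFraction = 0, seed = 1L) {
  if (is.character(tree)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                     error = function(e) NULL)
    if (is.null(tree) || is.null(tree$edge))
      stop("malformed newick tree")
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (nColumns < 1) stop("empty alignment: nColumns must be >= 1")
  if (rateMultiplier <= 0) stop("rateMultiplier must be > 0")
  if (missingFraction < 0 || missingFraction >= 1)
    stop("missingFraction must be in [0, 1)")
  simOne <- function(mult) {
    nt <- length(tree$tip.label)
    root <- nt + 1L
    states <- matrix(NA_integer_, nrow = nt + tree$Nnode, ncol = nColumns)
    states[root, ] <- sample.int(4L, nColumns, replace = TRUE)
    ord <- rev(ape::postorder(tree))
    for (k in ord) {
      par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      t <- tree$edge.length[k] * mult
      pchg <- 0.75 * (1 - exp(-4 * t / 3))
      chg <- stats::runif(nColumns) < pchg
      s <- states[par, ]
      off <- sample.int(3L, nColumns, replace = TRUE)
      s[chg] <- ((s[chg] - 1L + off[chg]) %% 4L) + 1L
      states[child, ] <- s
    }
    m <- matrix(c("A", "C", "G", "T")[states[seq_len(nt), ]], nrow = nt)
    if (missingFraction > 0)
      m[matrix(stats::runif(length(m)) < missingFraction,
               nrow = nt)] <- "N"
    rownames(m) <- tree$tip.label
    .aln_from_matrix(m)
  }
  .with_seed(seed, {
    alnA <- simOne(1)
    alnB <- simOne(rateMultiplier)
    list(alnA = alnA, alnB = alnB, tree = tree)
  })
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper producing every input the downstream pipeline needs:
#' karyotypes and synteny, raw recombination tracks, genes, orthogroups and
#' pathways, together with the planted ground truth.
#'
#' @param config a [simConfig()].
#' @param genes also simulate genes/pathways (default TRUE).
#' @return list with `config`, `karyo`, `rawMaps`, and (optionally)
#'   `genes`.
#' @export
simulateStudy <- function(config = simConfig(), genes = TRUE) {
  karyo <- simulateKaryotypes(config)
  rawMaps <- simulateRecombinationLandscape(karyo, config)
  res <- list(config = config, karyo = karyo, rawMaps = rawMaps)
  if (genes) res$genes <- simulateGenesAndPathways(karyo, config)
  res
}
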