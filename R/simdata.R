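# Seeded generators for every input the pipeline consumes: two-line
# enriched-library reads with known SSR/TE truth, F2 populations from a
# true map, and quantitative / epistatic phenotypes.

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(len) paste(sample(.BASES, len, replace = TRUE),
                                collapse = "")

# substitution errors, i.i.d. per base; indels optional and off by
# default so repeat counts stay exact in reads
.mutateRead <- function(seq, subRate, indelRate = 0) {
  if (subRate <= 0 && indelRate <= 0) return(seq)
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  hit <- which(runif(n) < subRate)
  for (i in hit) b[i] <- sample(setdiff(.BASES, b[i]), 1L)
  if (indelRate > 0) {
    u <- runif(n)
    del <- u < indelRate / 2
    ins <- u >= indelRate / 2 & u < indelRate
    if (any(ins))
      b[ins] <- paste0(b[ins], vapply(seq_len(sum(ins)),
                                      function(i) sample(.BASES, 1L),
                                      character(1)))
    if (any(del)) b <- b[!del]
  }
  paste(b, collapse = "")
}

# canonical 20-mers of a locus' two flanks (both strands)
.locusKmers <- function(flanks, k = 20L) {
  km <- unlist(lapply(flanks, .kmerSet, k = k), use.names = FALSE)
  rc <- .revcomp(km)
  unique(pmin(km, rc))
}

# draw flanks for all loci, resampling any locus that shares a 20-mer
# with another so clusters cannot merge by chance
.drawUniqueFlanks <- function(nLoci, flankLen) {
  flanks <- replicate(nLoci, c(.randSeq(flankLen), .randSeq(flankLen)),
                      simplify = FALSE)
  for (it in seq_len(100L)) {
    kms <- lapply(flanks, .locusKmers)
    tab <- table(unlist(kms, use.names = FALSE))
    dupKm <- names(tab)[tab > 1L]
    if (!length(dupKm)) return(flanks)
    clash <- which(vapply(kms, function(x) any(x %in% dupKm), logical(1)))
    # keep the first locus of each clashing set, redraw the rest
    redraw <- clash[-1L]
    if (!length(redraw)) redraw <- clash
    for (i in redraw)
      flanks[[i]] <- c(.randSeq(flankLen), .randSeq(flankLen))
  }
  stop("could not draw flanks without shared 20-mers")
}

#' Simulate enriched-library reads from two lines
#'
#' Generates SSR-locus and TE-site reads for two inbred lines with full
#' ground truth. For a polymorphic SSR locus the lines carry different
#' repeat counts of the same motif; for a non-polymorphic locus the
#' counts are equal. Each TE site emits junction reads (flank +
#' transposon + flank) only from the line(s) carrying the insertion,
#' emulating a transposon-enrichment library. Flanks are i.i.d. uniform
#' over ACGT, screened so no two loci share a 20-mer. Reads carry i.i.d.
#' substitution errors at `readErrorRate`. The seed fully determines the
#' output, byte for byte.
#'
#' Read identifiers follow `<line>|<locus>|<readIdx>`.
#'
#' @param cfg a [SimConfig-class].
#' @param teConsensus optional transposon consensus; when `NULL` and TE
#'   sites are requested, a 210-bp consensus with 15-bp terminal
#'   inverted repeats is generated from the seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateTwoLineReads <- function(cfg, teConsensus = NULL) {
  methods::validObject(cfg)
  for (m in names(cfg@motifPool)) canonicalMotif(m)  # rejects non-ACGT etc.
  minUnitThr <- 6L
  if (cfg@repeatCountRange[1L] < minUnitThr)
    warning("repeatCountRange can produce tracts below the detection ",
            "minimum (", minUnitThr, " copies for dinucleotides)")
  set.seed(cfg@seed)
  lines <- cfg@lineNames

  if (is.null(teConsensus) && cfg@nTeSites > 0L) {
    tir <- .randSeq(15L)
    teConsensus <- paste0(tir, .randSeq(180L), .revcomp(tir))
  }
  if (is.null(teConsensus)) teConsensus <- ""

  nLoci <- cfg@nSsrLoci + cfg@nTeSites
  flanks <- if (nLoci > 0L) .drawUniqueFlanks(nLoci, cfg@flankLen) else list()

  reads <- character(0)
  ids <- character(0)
  emit <- function(template, locus, line) {
    for (ri in seq_len(cfg@readsPerLocusPerLine)) {
      reads[[length(reads) + 1L]] <<-
        .mutateRead(template, cfg@readErrorRate, cfg@indelRate)
      ids[[length(ids) + 1L]] <<- paste(line, locus, ri, sep = "|")
    }
  }

  ssrRows <- list()
  if (cfg@nSsrLoci > 0L) {
    motifs <- sample(names(cfg@motifPool), cfg@nSsrLoci, replace = TRUE,
                     prob = cfg@motifPool)
    poly <- runif(cfg@nSsrLoci) < cfg@fracPolymorphic
    for (i in seq_len(cfg@nSsrLoci)) {
      locus <- sprintf("ssr_%04d", i)
      fl <- flanks[[i]]
      cnt1 <- sample(seq.int(cfg@repeatCountRange[1L],
                             cfg@repeatCountRange[2L]), 1L)
      cnt2 <- cnt1
      if (poly[i]) {
        delta <- sample(1:2, 1L) * sample(c(-1L, 1L), 1L)
        cnt2 <- cnt1 + delta
        if (cnt2 > cfg@repeatCountRange[2L] ||
            cnt2 < cfg@repeatCountRange[1L])
          cnt2 <- cnt1 - delta
      }
      cnts <- c(cnt1, cnt2)
      for (li in 1:2)
        emit(paste0(fl[1L], strrep(motifs[i], cnts[li]), fl[2L]),
             locus, lines[li])
      ssrRows[[i]] <- data.frame(locus = locus, motif = motifs[i],
                                 flank_left = fl[1L], flank_right = fl[2L],
                                 count_line1 = cnt1, count_line2 = cnt2,
                                 polymorphic = cnt1 != cnt2)
    }
  }

  teRows <- list()
  if (cfg@nTeSites > 0L) {
    specific <- runif(cfg@nTeSites) < cfg@fracTeLineSpecific
    for (i in seq_len(cfg@nTeSites)) {
      site <- sprintf("te_%04d", i)
      fl <- flanks[[cfg@nSsrLoci + i]]
      present <- c(TRUE, TRUE)
      if (specific[i]) {
        present <- c(FALSE, FALSE)
        present[sample(1:2, 1L)] <- TRUE
      }
      template <- paste0(fl[1L], teConsensus, fl[2L])
      for (li in which(present)) emit(template, site, lines[li])
      teRows[[i]] <- data.frame(locus = site, flank_left = fl[1L],
                                flank_right = fl[2L],
                                in_line1 = present[1L],
                                in_line2 = present[2L],
                                line_specific = specific[i])
    }
  }

  names(reads) <- ids
  truth <- new("SimTruth",
               ssr = if (length(ssrRows)) do.call(rbind, ssrRows)
                     else data.frame(),
               te = if (length(teRows)) do.call(rbind, teRows)
                    else data.frame(),
               teConsensus = teConsensus, lines = lines)
  list(reads = reads, truth = truth)
}

.asTruthMap <- function(map) {
  if (methods::is(map, "LinkageMap")) map <- mapTable(map)
  stopifnot(all(c("group", "locus", "position_cM") %in% names(map)))
  for (g in unique(map$group)) {
    p <- map$position_cM[map$group == g]
    if (any(p < 0) || is.unsorted(p, strictly = FALSE))
      stop("positions must be non-negative and increasing within a group")
  }
  map
}

#' Simulate an F2 genotype matrix from a true map
#'
#' Each individual is formed from two independent gametes; each gamete
#' is a Markov walk along every linkage group that recombines between
#' adjacent loci with probability equal to the inverse Haldane transform
#' of the cM interval (no crossover interference). Segregation
#' distortion, when requested, is applied as post-hoc viability
#' rejection sampling. Dominant observation and random missingness are
#' applied after the true genotypes are drawn.
#'
#' @param map a `data.frame` with `group`, `locus`, `position_cM` (or a
#'   [LinkageMap-class]).
#' @param n number of F2 individuals (>= 2).
#' @param distortion optional named list: locus -> viability weights
#'   `c(a, h, b)` in \[0, 1\] scale (an individual survives with
#'   probability proportional to the product of its weights).
#' @param missingRate per-cell probability of a missing code.
#' @param seed integer seed.
#' @param obsMode optional named character vector: locus ->
#'   `"dominant_a"` (report `a` vs `c`) or `"dominant_b"` (`b` vs `d`);
#'   unlisted loci are codominant.
#' @param qtlPositions optional data.frame (`group`, `position_cM`,
#'   `name`) of hidden loci to co-simulate; their true codominant
#'   genotypes are returned in the `"qtlGeno"` attribute and are not
#'   subject to `obsMode` or missingness.
#' @return a [GenotypeMatrix-class]; attributes `qtlGeno` and
#'   `truthMap`.
#' @export
simulateF2 <- function(map, n, distortion = NULL, missingRate = 0,
                       seed = 1L, obsMode = NULL, qtlPositions = NULL) {
  map <- .asTruthMap(map)
  if (n < 2L) stop("need at least 2 individuals")
  set.seed(as.integer(seed))
  full <- map
  full$hidden <- FALSE
  if (!is.null(qtlPositions)) {
    q <- data.frame(group = qtlPositions$group,
                    locus = qtlPositions$name,
                    position_cM = qtlPositions$position_cM, hidden = TRUE)
    full <- rbind(full[, c("group", "locus", "position_cM", "hidden")], q)
  } else {
    full <- full[, c("group", "locus", "position_cM", "hidden")]
  }
  full <- full[order(match(full$group, unique(full$group)),
                     full$position_cM), , drop = FALSE]

  groups <- split(full, factor(full$group, levels = unique(full$group)))
  drawOne <- function() {
    g <- unlist(lapply(groups, function(gg) {
      r <- haldaneR(diff(gg$position_cM))
      a1 <- integer(nrow(gg))
      a2 <- integer(nrow(gg))
      a1[1L] <- sample(0:1, 1L)
      a2[1L] <- sample(0:1, 1L)
      if (nrow(gg) > 1L) {
        f1 <- runif(length(r)) < r
        f2 <- runif(length(r)) < r
        a1[-1L] <- (a1[1L] + cumsum(f1)) %% 2L
        a2[-1L] <- (a2[1L] + cumsum(f2)) %% 2L
      }
      a1 + a2
    }), use.names = FALSE)
    setNames(g, full$locus)
  }
  survives <- function(g) {
    if (is.null(distortion)) return(TRUE)
    pr <- 1
    for (l in names(distortion)) {
      w <- distortion[[l]]
      pr <- pr * (w[g[[l]] + 1L] / max(w))
    }
    runif(1L) < pr
  }
  G <- matrix(0L, n, nrow(full))
  filled <- 0L
  guard <- 0L
  while (filled < n) {
    guard <- guard + 1L
    if (guard > 1000L * n) stop("viability selection rejects everything")
    g <- drawOne()
    if (survives(g)) {
      filled <- filled + 1L
      G[filled, ] <- g
    }
  }
  codes <- matrix(c("a", "h", "b")[G + 1L], n, ncol(G))
  colnames(codes) <- full$locus
  rownames(codes) <- sprintf("ind_%03d", seq_len(n))

  hidden <- full$hidden
  qtlGeno <- codes[, hidden, drop = FALSE]
  codes <- codes[, !hidden, drop = FALSE]
  if (!is.null(obsMode)) {
    for (l in names(obsMode)) {
      if (!(l %in% colnames(codes))) stop("obsMode names unknown locus ", l)
      v <- codes[, l]
      if (obsMode[[l]] == "dominant_a") v[v %in% c("h", "b")] <- "c"
      else if (obsMode[[l]] == "dominant_b") v[v %in% c("a", "h")] <- "d"
      else stop("obsMode must be dominant_a or dominant_b")
      codes[, l] <- v
    }
  }
  if (missingRate > 0)
    codes[runif(length(codes)) < missingRate] <- "-"
  out <- GenotypeMatrix(codes)
  attr(out, "qtlGeno") <- qtlGeno
  attr(out, "truthMap") <- map
  out
}

.qtlCodes <- function(geno, locus) {
  m <- genoCodes(geno)
  if (locus %in% colnames(m)) return(m[, locus])
  q <- attr(geno, "qtlGeno")
  if (!is.null(q) && locus %in% colnames(q)) return(q[, locus])
  stop("phenotype model names unknown locus '", locus, "'")
}

#' Simulate phenotypes on an F2 population
#'
#' Two trait models. The quantitative model sums additive and dominance
#' contributions over QTLs, `sum(a x_a + d x_d) + N(0, sigma)`, with
#' `x_a` in \{-1, 0, +1\} (second-parent allele dosage minus 1) and
#' `x_d` = 1 for heterozygotes. The epistatic model emulates a
#' double-recessive two-gene trait such as the seed oleic/linoleic
#' ratio: only individuals homozygous for the designated allele at BOTH
#' loci draw from the high phenotype class, everyone else from the low
#' class. Default class parameters (low 1.0 +/- 1.5, high 30 +/- 4)
#' follow the spread seen in segregating seed O/L measurements, where
#' the low class sits near the normal-cultivar value and the high class
#' reaches the mutant parent's range.
#'
#' @param geno a [GenotypeMatrix-class] from [simulateF2()] (hidden QTL
#'   genotypes in its `qtlGeno` attribute are honored).
#' @param model list. Quantitative: `type = "quantitative"`, `qtls` =
#'   data.frame(`locus`, `a`, `d`), `sigma`. Epistatic: `type =
#'   "epistatic"`, `loci` (two ids), `genotype` (the required homozygous
#'   code, default `"b"`), `lowMean`, `highMean`, `lowSd`, `highSd`.
#' @param seed integer seed.
#' @param trait name of the phenotype column.
#' @return data.frame with `id` and the trait column.
#' @export
simulatePhenotypes <- function(geno, model, seed = 1L, trait = "trait") {
  set.seed(as.integer(seed))
  ids <- rownames(genoCodes(geno))
  n <- length(ids)
  if (model$type == "quantitative") {
    qtls <- model$qtls
    sigma <- if (is.null(model$sigma)) 1 else model$sigma
    y <- rnorm(n, 0, sigma)
    for (k in seq_len(nrow(qtls))) {
      g <- .qtlCodes(geno, qtls$locus[k])
      if (!all(g %in% c("a", "h", "b")))
        stop("QTL locus '", qtls$locus[k], "' must be codominant")
      xa <- c(a = -1, h = 0, b = 1)[g]
      xd <- as.numeric(g == "h")
      y <- y + qtls$a[k] * xa + qtls$d[k] * xd
    }
  } else if (model$type == "epistatic") {
    stopifnot(length(model$loci) == 2L)
    hom <- if (is.null(model$genotype)) "b" else model$genotype
    lowMean <- if (is.null(model$lowMean)) 1 else model$lowMean
    highMean <- if (is.null(model$highMean)) 30 else model$highMean
    lowSd <- if (is.null(model$lowSd)) 1.5 else model$lowSd
    highSd <- if (is.null(model$highSd)) 4 else model$highSd
    g1 <- .qtlCodes(geno, model$loci[1L])
    g2 <- .qtlCodes(geno, model$loci[2L])
    high <- g1 == hom & g2 == hom
    y <- ifelse(high, rnorm(n, highMean, highSd), rnorm(n, lowMean, lowSd))
  } else stop("unknown phenotype model type '", model$type, "'")
  out <- data.frame(id = ids, y = as.numeric(y))
  names(out)[2L] <- trait
  out
}
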