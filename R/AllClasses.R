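#' @import methods
#' @importFrom stats pchisq pf quantile rbinom rnorm runif setNames
#'   aggregate lm.fit var na.omit
#' @importFrom utils combn head read.table write.table
NULL

GENO_CODES <- c("a", "h", "b", "c", "d", "-")

#' Simulation configuration for two-line library reads
#'
#' Holds every tunable of the read simulator: number of SSR loci and MITE
#' insertion sites, the fraction of SSR loci whose repeat count differs
#' between the two lines, the fraction of insertion sites present in only
#' one line, motif pool, repeat-count range, flank length, per-base
#' substitution (and optional indel) error rates, read depth and seed.
#' The seed fully determines the output.
#'
#' @slot nSsrLoci integer, number of simulated SSR loci.
#' @slot fracPolymorphic fraction of SSR loci with differing repeat counts.
#' @slot motifPool named numeric vector of canonical motif classes and
#'   sampling weights.
#' @slot repeatCountRange integer pair, inclusive range of repeat counts.
#' @slot flankLen length in bases of each flank around the feature.
#' @slot nTeSites integer, number of transposon insertion sites.
#' @slot fracTeLineSpecific fraction of insertion sites carried by exactly
#'   one line.
#' @slot readErrorRate per-base substitution probability.
#' @slot indelRate per-base indel probability (default 0 so repeat counts
#'   stay exact in reads).
#' @slot readsPerLocusPerLine read depth per locus and line.
#' @slot lineNames names of the two lines, used as read-id prefixes.
#' @slot seed integer random seed.
#' @export
setClass("SimConfig", representation(
  nSsrLoci = "integer",
  fracPolymorphic = "numeric",
  motifPool = "numeric",
  repeatCountRange = "integer",
  flankLen = "integer",
  nTeSites = "integer",
  fracTeLineSpecific = "numeric",
  readErrorRate = "numeric",
  indelRate = "numeric",
  readsPerLocusPerLine = "integer",
  lineNames = "character",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  fr <- c(fracPolymorphic = object@fracPolymorphic,
          fracTeLineSpecific = object@fracTeLineSpecific,
          readErrorRate = object@readErrorRate,
          indelRate = object@indelRate)
  bad <- fr < 0 | fr > 1 | !is.finite(fr)
  if (any(bad))
    msg <- c(msg, paste0("fractions must lie in [0,1]: ",
                         paste(names(fr)[bad], collapse = ", ")))
  if (object@nSsrLoci < 0L || object@nTeSites < 0L)
    msg <- c(msg, "locus counts must be non-negative")
  if (length(object@repeatCountRange) != 2L ||
      any(object@repeatCountRange < 1L) ||
      diff(object@repeatCountRange) < 0L)
    msg <- c(msg, "repeatCountRange must be an increasing positive pair")
  if (object@flankLen < 54L)
    msg <- c(msg, "flankLen must be >= 54 (twice the maximum primer length)")
  if (length(object@motifPool) == 0L || any(object@motifPool < 0) ||
      sum(object@motifPool) <= 0)
    msg <- c(msg, "motifPool needs positive weights")
  if (is.null(names(object@motifPool)) ||
      any(grepl("[^ACGT]", names(object@motifPool))))
    msg <- c(msg, "motifPool motifs must be named ACGT strings")
  if (length(object@lineNames) != 2L ||
      anyDuplicated(object@lineNames) ||
      any(grepl("[|]", object@lineNames)))
    msg <- c(msg, "lineNames must be two distinct labels without '|'")
  if (object@readsPerLocusPerLine < 1L)
    msg <- c(msg, "readsPerLocusPerLine must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults describe a screening experiment of the kind the package
#' targets: a few hundred enriched-library loci from two inbred lines,
#' roughly 30% of SSR loci polymorphic, 43% of MITE insertion sites
#' line-specific, Sanger-scale substitution error of 0.5%, and four reads
#' per locus and line.
#'
#' @param nSsrLoci,fracPolymorphic,motifPool,repeatCountRange,flankLen
#'   see the class slots.
#' @param nTeSites,fracTeLineSpecific,readErrorRate,indelRate see slots.
#' @param readsPerLocusPerLine,lineNames,seed see slots.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nSsrLoci = 20, nTeSites = 5, seed = 7)
#' cfg
#' @export
SimConfig <- function(nSsrLoci = 200L,
                      fracPolymorphic = 0.3,
                      motifPool = c(CT = 0.36, AC = 0.28, CTT = 0.12,
                                    ATT = 0.12, ACAT = 0.12),
                      repeatCountRange = c(8L, 16L),
                      flankLen = 150L,
                      nTeSites = 100L,
                      fracTeLineSpecific = 0.43,
                      readErrorRate = 0.005,
                      indelRate = 0,
                      readsPerLocusPerLine = 4L,
                      lineNames = c("line1", "line2"),
                      seed = 1L) {
  new("SimConfig",
      nSsrLoci = as.integer(nSsrLoci),
      fracPolymorphic = fracPolymorphic,
      motifPool = motifPool,
      repeatCountRange = as.integer(repeatCountRange),
      flankLen = as.integer(flankLen),
      nTeSites = as.integer(nTeSites),
      fracTeLineSpecific = fracTeLineSpecific,
      readErrorRate = readErrorRate,
      indelRate = indelRate,
      readsPerLocusPerLine = as.integer(readsPerLocusPerLine),
      lineNames = lineNames,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSsrLoci, "SSR loci (",
      round(100 * object@fracPolymorphic, 1), "% polymorphic ), ",
      object@nTeSites, " TE sites (",
      round(100 * object@fracTeLineSpecific, 1), "% line-specific )\n",
      sep = "")
  cat("  motifs:", paste(names(object@motifPool), collapse = ", "),
      "| repeats", paste(object@repeatCountRange, collapse = "-"),
      "| flank", object@flankLen, "bp\n")
  cat("  error", object@readErrorRate, "| depth",
      object@readsPerLocusPerLine, "reads/line/locus | lines",
      paste(object@lineNames, collapse = " vs "),
      "| seed", object@seed, "\n")
})

#' Ground truth of a simulated two-line experiment
#'
#' Per SSR locus: flanks, motif class, the repeat count carried by each
#' line and the polymorphism flag. Per TE site: flanks and per-line
#' presence. Every simulated read traces back to exactly one truth locus
#' through its identifier.
#'
#' @slot ssr data.frame of SSR locus truth.
#' @slot te data.frame of TE site truth.
#' @slot teConsensus the transposon consensus sequence used.
#' @slot lines the two line names.
#' @export
setClass("SimTruth", representation(
  ssr = "data.frame",
  te = "data.frame",
  teConsensus = "character",
  lines = "character"
))

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@ssr), "SSR loci,", nrow(object@te),
      "TE sites; lines", paste(object@lines, collapse = " vs "), "\n")
  if (nrow(object@ssr))
    cat("  polymorphic SSR:", sum(object@ssr$polymorphic), "\n")
  if (nrow(object@te))
    cat("  line-specific TE:", sum(object@te$line_specific), "\n")
})

#' @describeIn SimTruth-class SSR locus truth table.
#' @param x,object a `SimTruth`.
#' @export
ssrTruth <- function(x) x@ssr

#' @describeIn SimTruth-class TE site truth table.
#' @export
teTruth <- function(x) x@te

#' F2 genotype matrix
#'
#' A rectangular individuals-by-loci matrix of single-character genotype
#' codes: `a` (homozygote for the first parental allele), `h`
#' (heterozygote), `b` (homozygote for the second parental allele), `c`
#' (dominant "not-a", i.e. `h` or `b`), `d` (dominant "not-b"), and `-`
#' for missing. Each locus must be consistently codominant (`a/h/b`) or
#' dominant (`a/c` or `b/d`); mixed coding within a locus is rejected.
#'
#' @slot codes character matrix with individual row names and locus
#'   column names.
#' @export
setClass("GenotypeMatrix", representation(codes = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@codes
  if (!is.character(m)) return("codes must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("codes needs individual row names and locus column names")
  bad <- !(m %in% GENO_CODES)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("illegal genotype code '%s' at individual '%s', locus '%s'",
                   m[bad][1L], rownames(m)[w[1L]], colnames(m)[w[2L]]))
  }
  for (j in seq_len(ncol(m))) {
    obs <- setdiff(unique(m[, j]), "-")
    ok <- all(obs %in% c("a", "h", "b")) || all(obs %in% c("a", "c")) ||
      all(obs %in% c("b", "d"))
    if (!ok)
      return(sprintf("locus '%s' mixes codominant and dominant codes (%s)",
                     colnames(m)[j], paste(sort(obs), collapse = ",")))
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param codes character matrix of genotype codes (individuals x loci),
#'   with dimnames.
#' @return A validated [GenotypeMatrix-class].
#' @examples
#' m <- matrix(c("a", "h", "b", "h"), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' GenotypeMatrix(m)
#' @export
GenotypeMatrix <- function(codes) new("GenotypeMatrix", codes = codes)

#' @describeIn GenotypeMatrix-class the underlying character matrix.
#' @param x,object a `GenotypeMatrix`.
#' @export
genoCodes <- function(x) x@codes

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@codes))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dimnames", "GenotypeMatrix", function(x) dimnames(x@codes))

#' @rdname GenotypeMatrix-class
#' @param i,j,drop subsetting indices; `drop` is ignored.
#' @param ... unused.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  GenotypeMatrix(x@codes[i, j, drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@codes)
  cat("GenotypeMatrix:", d[1L], "individuals x", d[2L], "loci\n")
  tp <- table(vapply(seq_len(d[2L]), function(j)
    locusType(object@codes[, j]), character(1)))
  cat("  locus types:", paste(names(tp), tp, sep = "=", collapse = ", "), "\n")
  cat("  missing:", round(100 * mean(object@codes == "-"), 2), "%\n")
})

#' Classify a genotype column as codominant or dominant
#'
#' @param column character vector of genotype codes for one locus.
#' @return `"codominant"`, `"dominant_a"` (codes a vs c) or
#'   `"dominant_b"` (codes b vs d).
#' @export
locusType <- function(column) {
  obs <- setdiff(unique(column), "-")
  if (all(obs %in% c("a", "c")) && "c" %in% obs) return("dominant_a")
  if (all(obs %in% c("b", "d")) && "d" %in% obs) return("dominant_b")
  if (all(obs %in% c("a", "h", "b"))) return("codominant")
  stop("locus mixes incompatible genotype codes: ",
       paste(sort(obs), collapse = ","))
}

#' F2 linkage map
#'
#' Ordered loci in linkage groups with cumulative Haldane positions (cM)
#' and per-locus segregation test results.
#'
#' @slot loci data.frame with columns `group`, `locus`, `position_cM`,
#'   `chi2`, `p`, `df`, `distorted`.
#' @export
setClass("LinkageMap", representation(loci = "data.frame"))

setValidity("LinkageMap", function(object) {
  d <- object@loci
  need <- c("group", "locus", "position_cM", "chi2", "p", "df", "distorted")
  if (!all(need %in% names(d)))
    return(paste("loci table needs columns:", paste(need, collapse = ", ")))
  for (g in unique(d$group)) {
    p <- d$position_cM[d$group == g]
    if (length(p) && (p[1L] != 0 || is.unsorted(p)))
      return(sprintf("group '%s': positions must start at 0 and be non-decreasing", g))
  }
  TRUE
})

#' @describeIn LinkageMap-class the per-locus table.
#' @param x,object a `LinkageMap`.
#' @export
mapTable <- function(x) x@loci

#' @describeIn LinkageMap-class group names in map order.
#' @export
groupNames <- function(x) unique(x@loci$group)

setMethod("show", "LinkageMap", function(object) {
  d <- object@loci
  g <- unique(d$group)
  len <- vapply(g, function(gg) max(d$position_cM[d$group == gg]), numeric(1))
  cat("LinkageMap:", length(g), "groups,", nrow(d), "loci,",
      round(sum(len), 1), "cM total\n")
  for (gg in head(g, 8L))
    cat(sprintf("  %s: %d loci, %.1f cM\n", gg, sum(d$group == gg),
                max(d$position_cM[d$group == gg])))
  if (length(g) > 8L) cat("  ...\n")
})

#' Result of a QTL genome scan
#'
#' @slot profile data.frame with one row per test position: `group`,
#'   `position_cM`, `lod`, `additive`, `dominance`.
#' @slot threshold genome-wide LOD threshold (NA until set).
#' @slot peaks data.frame of declared peaks with support intervals and
#'   variance explained.
#' @slot n number of phenotyped individuals used.
#' @export
setClass("QtlScanResult", representation(
  profile = "data.frame",
  threshold = "numeric",
  peaks = "data.frame",
  n = "integer"
))

#' @describeIn QtlScanResult-class the LOD/effect profile.
#' @param x,object a `QtlScanResult`.
#' @export
scanProfile <- function(x) x@profile

#' @describeIn QtlScanResult-class declared peaks.
#' @export
scanPeaks <- function(x) x@peaks

setMethod("show", "QtlScanResult", function(object) {
  cat("QtlScanResult:", nrow(object@profile), "positions, n =", object@n, "\n")
  cat("  max LOD:", round(max(object@profile$lod), 2))
  if (!is.na(object@threshold))
    cat("  threshold:", round(object@threshold, 2))
  cat("\n")
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks, row.names = FALSE)
  }
})

#' A cluster of reads sharing flanking sequence
#'
#' Reads from both lines grouped into one putative genomic locus by
#' flanking-sequence identity (the feature interval is excised before
#' alignment). The unit on which polymorphism is classified.
#'
#' @slot id cluster identifier.
#' @slot members data.frame: `read`, `line`, `orientation`.
#' @slot observations data.frame: `read`, `line`, `type` (SSR/TE),
#'   `motif` (canonical class, NA for TE) and `value` (repeat count, or 1
#'   for TE presence).
#' @slot repRead identifier of the representative read.
#' @slot repSeq representative read sequence (representative strand).
#' @slot repFeature 0-based half-open feature interval within `repSeq`.
#' @export
setClass("SeqCluster", representation(
  id = "character",
  members = "data.frame",
  observations = "data.frame",
  repRead = "character",
  repSeq = "character",
  repFeature = "numeric"
))

setValidity("SeqCluster", function(object) {
  if (anyDuplicated(object@members$read))
    return("a read may belong to a cluster only once")
  if (!all(object@observations$read %in% object@members$read))
    return("observations refer to non-member reads")
  TRUE
})

setMethod("show", "SeqCluster", function(object) {
  tab <- table(object@members$line)
  cat("SeqCluster", object@id, ":", nrow(object@members), "reads (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  if (nrow(object@observations)) {
    o <- object@observations
    cat("  features:", paste(unique(o$type), collapse = "+"),
        if (!all(is.na(o$motif))) paste("motif", unique(stats::na.omit(o$motif))),
        "\n")
  }
})

#' @describeIn SeqCluster-class member table.
#' @param x a `SeqCluster`.
#' @export
clusterMembers <- function(x) x@members

#' @describeIn SeqCluster-class feature observation table.
#' @export
clusterObservations <- function(x) x@observations
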