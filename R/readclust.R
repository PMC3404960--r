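# Clustering of two-line library reads by flanking-sequence identity.
# Stands in for whole-read contig assembly: the SSR/TE interval is
# excised before alignment so a repeat-length difference between lines
# cannot destroy flank identity.

.lineOf <- function(readIds) {
  has <- grepl("|", readIds, fixed = TRUE)
  out <- rep(NA_character_, length(readIds))
  out[has] <- sub("\\|.*$", "", readIds[has])
  out
}

.kmerSet <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq.int(k, n))
}

#' Canonical k-mer fingerprints of a read's flanks
#'
#' Strand-minimal k-mers drawn from the two flanks of the feature
#' interval; no returned k-mer overlaps the feature, and a read and its
#' reverse complement yield identical key sets. Used as a candidate-pair
#' prefilter before alignment.
#'
#' @param seq one read sequence (character).
#' @param featureStart,featureEnd 0-based half-open feature interval.
#' @param k k-mer size.
#' @return character vector of canonical k-mer keys (possibly empty).
#' @export
flankFingerprints <- function(seq, featureStart, featureEnd, k = 15L) {
  stopifnot(featureStart >= 0, featureEnd >= featureStart,
            featureEnd <= nchar(seq))
  left <- substring(seq, 1L, featureStart)
  right <- substring(seq, featureEnd + 1L, nchar(seq))
  km <- c(.kmerSet(left, k), .kmerSet(right, k))
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

.flankConcat <- function(seq, start, end) {
  paste0(substring(seq, 1L, start), substring(seq, end + 1L, nchar(seq)))
}

# identity over excised flanks: matches / aligned columns (gaps count
# as columns) of a global alignment of the left+right flank
# concatenations, best of the two orientations.
#
# Fast path: the left flanks of two co-locus reads are anchored at
# their outer ends, so a prefix-anchored (left) plus suffix-anchored
# (right) gap-free comparison yields a valid global alignment whose
# identity lower-bounds what the dynamic program can achieve; when that
# bound already clears `earlyAccept` the full alignment is skipped.
.anchoredBound <- function(la, ra, lb, rb) {
  pre <- function(a, b) {
    m <- min(nchar(a), nchar(b))
    if (m == 0L) return(0L)
    sum(utf8ToInt(substring(a, 1L, m)) == utf8ToInt(substring(b, 1L, m)))
  }
  suf <- function(a, b) {
    m <- min(nchar(a), nchar(b))
    if (m == 0L) return(0L)
    sum(utf8ToInt(substring(a, nchar(a) - m + 1L, nchar(a))) ==
          utf8ToInt(substring(b, nchar(b) - m + 1L, nchar(b))))
  }
  matches <- pre(la, lb) + suf(ra, rb)
  cols <- max(nchar(la), nchar(lb)) + max(nchar(ra), nchar(rb))
  if (cols == 0L) 0 else matches / cols
}

.flankIdentity <- function(la, ra, lb, rb, earlyAccept = 1.01) {
  bndF <- .anchoredBound(la, ra, lb, rb)
  if (bndF >= earlyAccept)
    return(list(identity = bndF,
                cols = max(nchar(la), nchar(lb)) + max(nchar(ra), nchar(rb)),
                orientation = "+"))
  bndR <- .anchoredBound(la, ra, .revcomp(rb), .revcomp(lb))
  if (bndR >= earlyAccept)
    return(list(identity = bndR,
                cols = max(nchar(la), nchar(rb)) + max(nchar(ra), nchar(lb)),
                orientation = "-"))
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  score <- function(p, s) {
    if (nchar(p) == 0L || nchar(s) == 0L)
      return(c(ident = 0, cols = max(nchar(p), nchar(s))))
    al <- Biostrings::pairwiseAlignment(p, s, type = "global",
                                        substitutionMatrix = sub,
                                        gapOpening = 4, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::pattern(al)))
    c(ident = Biostrings::nmatch(al) / cols, cols = cols)
  }
  fa <- paste0(la, ra)
  fb <- paste0(lb, rb)
  fwd <- score(fa, fb)
  rev <- score(fa, .revcomp(fb))
  if (fwd[["ident"]] >= rev[["ident"]])
    list(identity = fwd[["ident"]], cols = fwd[["cols"]], orientation = "+")
  else
    list(identity = rev[["ident"]], cols = rev[["cols"]], orientation = "-")
}

#' Cluster annotated reads into putative loci
#'
#' Reads carrying a feature annotation (an SSR tract or TE junction) are
#' grouped into clusters representing one genomic locus. Pairs sharing at
#' least `minSharedKeys` canonical flank k-mers are aligned globally over
#' their flanks (feature excised); pairs reaching `minIdentity` over at
#' least `minAlignedCols` aligned columns (gaps counted as columns) are
#' connected, and clusters are the connected components (single linkage).
#' Reads without an annotation are ignored, mirroring the off-target
#' fraction of an enrichment library. Output is independent of input
#' order: clusters are identified by their lexicographically smallest
#' member read id and orientation is normalized to the representative
#' strand.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param annotations data.frame with columns `read`, `start`, `end`
#'   (0-based half-open feature interval) and optionally `type`, `motif`,
#'   `value` (repeat count or TE presence), one row per annotated read.
#' @param minIdentity identity threshold in (0.5, 1].
#' @param k fingerprint k-mer size.
#' @param minSharedKeys shared fingerprint keys required to attempt an
#'   alignment.
#' @param minAlignedCols minimum aligned columns for a valid comparison.
#' @return list of [SeqCluster-class] objects.
#' @export
clusterReads <- function(reads, annotations, minIdentity = 0.95, k = 15L,
                         minSharedKeys = 3L, minAlignedCols = 40L) {
  if (minIdentity <= 0.5 || minIdentity > 1)
    stop("minIdentity must lie in (0.5, 1]")
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  stopifnot(!is.null(names(reads)),
            all(c("read", "start", "end") %in% names(annotations)))
  if (anyDuplicated(annotations$read))
    stop("at most one feature annotation per read")
  ann <- annotations[annotations$read %in% names(reads), , drop = FALSE]
  ann <- ann[order(ann$read), , drop = FALSE]   # order-independence
  ids <- ann$read
  n <- length(ids)
  if (!n) return(list())
  seqs <- unname(reads[ids])
  if (!("type" %in% names(ann))) ann$type <- "SSR"
  if (!("motif" %in% names(ann))) ann$motif <- NA_character_
  if (!("value" %in% names(ann))) ann$value <- NA_real_

  flankL <- substring(seqs, 1L, ann$start)
  flankR <- substring(seqs, ann$end + 1L, nchar(seqs))
  fps <- lapply(seq_len(n), function(i)
    flankFingerprints(seqs[i], ann$start[i], ann$end[i], k))

  # candidate pairs by shared canonical k-mers
  keyDf <- data.frame(key = unlist(fps),
                      idx = rep(seq_len(n), lengths(fps)))
  byKey <- split(keyDf$idx, keyDf$key)
  byKey <- byKey[lengths(byKey) >= 2L & lengths(byKey) <= 200L]
  pairKeys <- unlist(lapply(byKey, function(v) {
    v <- sort.int(v)
    p <- combn(v, 2L)
    p[1L, ] * (n + 1) + p[2L, ]
  }), use.names = FALSE)
  if (length(pairKeys)) {
    cnt <- table(pairKeys)
    cand <- as.numeric(names(cnt)[cnt >= minSharedKeys])
  } else cand <- numeric(0)

  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- new.env(parent = emptyenv())
  for (pk in cand) {
    i <- as.integer(pk %/% (n + 1))
    j <- as.integer(pk %% (n + 1))
    al <- .flankIdentity(flankL[i], flankR[i], flankL[j], flankR[j],
                         earlyAccept = minIdentity)
    if (al$cols >= minAlignedCols && al$identity >= minIdentity) {
      assign(paste(i, j), al$orientation, envir = edges)
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  comp <- split(seq_len(n), roots)
  # deterministic ids: order components by smallest member read id
  comp <- comp[order(vapply(comp, function(v) min(ids[v]), character(1)))]

  lines <- .lineOf(ids)
  out <- vector("list", length(comp))
  for (ci in seq_along(comp)) {
    v <- comp[[ci]]
    rep_i <- v[order(ids[v])[1L]]
    orient <- vapply(v, function(i) {
      if (i == rep_i) return("+")
      e <- mget(c(paste(min(i, rep_i), max(i, rep_i))), envir = edges,
                ifnotfound = NA_character_)[[1L]]
      if (!is.na(e)) e
      else .flankIdentity(flankL[rep_i], flankR[rep_i], flankL[i],
                          flankR[i])$orientation
    }, character(1))
    out[[ci]] <- new("SeqCluster",
      id = sprintf("cluster_%04d", ci),
      members = data.frame(read = ids[v], line = lines[v],
                           orientation = orient),
      observations = data.frame(read = ids[v], line = lines[v],
                                type = ann$type[v], motif = ann$motif[v],
                                value = ann$value[v]),
      repRead = ids[rep_i],
      repSeq = seqs[rep_i],
      repFeature = c(ann$start[rep_i], ann$end[rep_i]))
  }
  out
}

# extend a tract interval outward over bases that continue its
# periodicity, tolerating `budget` mismatched bases per direction; this
# lets the excision cover a repeat region that a sequencing error has
# split into a detected run plus a residual run
# (a substitution breaks the lag-k comparison at two offsets, so a
# budget of 4 tolerates up to two errors per side)
.extendPeriodic <- function(seq, start, end, k, budget = 4L) {
  y <- utf8ToInt(seq)
  n <- length(y)
  i <- end            # 0-based exclusive end; next base is y[i + 1]
  mm <- budget
  while (i < n) {
    if (y[i + 1L] == y[i + 1L - k]) i <- i + 1L
    else if (mm > 0L) { mm <- mm - 1L; i <- i + 1L }
    else break
  }
  j <- start          # 0-based start; previous base is y[j]
  mm <- budget
  while (j > 0L) {
    if (y[j] == y[j + k]) j <- j - 1L
    else if (mm > 0L) { mm <- mm - 1L; j <- j - 1L }
    else break
  }
  c(j, i)
}

# repeat count of the whole repeat region: motif-length windows tiled
# outward from the detected tract's anchor. A perfect window always
# counts; a window with one mismatch counts only when the next window
# outward is perfect (an interior copy carrying a substitution error),
# so errored copies are recovered without annexing flank sequence.
.countCopies <- function(seq, start, k, unit) {
  y <- utf8ToInt(seq)
  u <- utf8ToInt(unit)
  n <- length(y)
  mmAt <- function(lo) sum(y[(lo + 1L):(lo + k)] != u)
  cnt <- 0L
  i <- start                       # 0-based; forward tiles [i, i+k)
  while (i + k <= n) {
    mm <- mmAt(i)
    if (mm == 0L ||
        (mm == 1L && i + 2L * k <= n && mmAt(i + k) == 0L)) {
      cnt <- cnt + 1L
      i <- i + k
    } else break
  }
  j <- start                       # backward tiles [j-k, j)
  while (j - k >= 0L) {
    mm <- mmAt(j - k)
    if (mm == 0L ||
        (mm == 1L && j - 2L * k >= 0L && mmAt(j - 2L * k) == 0L)) {
      cnt <- cnt + 1L
      j <- j - k
    } else break
  }
  cnt
}

#' Annotate reads with their dominant SSR tract
#'
#' Convenience glue between [findTracts()] and [clusterReads()]: each
#' read keeps its longest tract (ties to the smaller start); reads
#' without a tract get no annotation and are therefore ignored by the
#' clustering step. With `extendExcision` (the default) the annotated
#' interval is widened over any bases that continue the tract's
#' periodicity (tolerating up to two substitutions per side), so that a
#' repeat region split by a sequencing error is excised whole and the
#' flanks stay comparable across reads, and the reported repeat count
#' covers the whole region with error-carrying copies included (one
#' mismatch allowed per copy). Without it, interval and count are those
#' of the perfect tract exactly as found.
#'
#' @inheritParams findTracts
#' @param extendExcision widen the excised interval over error-split
#'   repeat residue.
#' @return annotation data.frame for [clusterReads()].
#' @export
ssrAnnotations <- function(x, minRepeats = c("2" = 6L, "3" = 5L, "4" = 5L),
                           extendExcision = TRUE) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  tr <- findTracts(x, minRepeats)
  if (!nrow(tr))
    return(data.frame(read = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      motif = character(0), value = numeric(0)))
  tr <- tr[order(tr$seqid, -tr$tract_len, tr$start), , drop = FALSE]
  tr <- tr[!duplicated(tr$seqid), , drop = FALSE]
  if (extendExcision) {
    for (i in seq_len(nrow(tr))) {
      k <- nchar(tr$observed_motif[i])
      s <- x[[tr$seqid[i]]]
      iv <- .extendPeriodic(s, tr$start[i], tr$end[i], k)
      tr$repeat_count[i] <- .countCopies(s, tr$start[i], k,
                                         tr$observed_motif[i])
      tr$start[i] <- iv[1L]
      tr$end[i] <- iv[2L]
    }
  }
  data.frame(read = tr$seqid, start = tr$start, end = tr$end, type = "SSR",
             motif = tr$motif, value = tr$repeat_count)
}
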