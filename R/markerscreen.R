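# Classification of read clusters into polymorphic / monomorphic /
# single-line marker candidates, for SSR repeat-length differences and
# cultivar-specific transposon insertions.

#' Round half away from zero
#'
#' Plain decimal rounding in which .5 always rounds up, the convention
#' used for the percentage and map-density bookkeeping tables here
#' (unlike base R's round-half-even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage with half-up rounding
#'
#' @param count numerator.
#' @param total denominator.
#' @param digits decimal places (default one, the table convention).
#' @return `100 * count / total`, rounded half-up.
#' @examples
#' percentHalfUp(126, 2952)  # 4.3
#' @export
percentHalfUp <- function(count, total, digits = 1L) {
  roundHalfUp(100 * count / total, digits)
}

.majorityValue <- function(v) {
  tab <- table(v)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) NA_real_ else as.numeric(top)
}

.candidateRow <- function(cluster, type, class, motif, obs1, obs2, lines) {
  data.frame(id = paste0(cluster@id, ".", type),
             cluster_id = cluster@id,
             marker_type = type,
             class = class,
             motif = ifelse(is.na(motif), "", motif),
             obs_line1 = paste(obs1, collapse = ","),
             obs_line2 = paste(obs2, collapse = ","),
             line1 = lines[1L], line2 = lines[2L],
             template = cluster@repSeq,
             feature_start = cluster@repFeature[1L],
             feature_end = cluster@repFeature[2L],
             stringsAsFactors = FALSE)
}

#' Classify an SSR cluster
#'
#' The core in silico polymorphism call for microsatellites: a cluster is
#' polymorphic iff the per-line consensus repeat counts (majority vote
#' within each line) differ, monomorphic iff they are equal, and
#' single-line if only one line contributed reads. Clusters whose members
#' disagree on the canonical motif class, or with a tied within-line
#' vote, are classified "conflicted" and excluded from candidate lists.
#'
#' @param cluster a [SeqCluster-class] whose observations carry SSR
#'   repeat counts.
#' @param lines character pair naming the two lines.
#' @param minReadsPerLine reads required before a line's consensus counts.
#' @return one-row data.frame (a marker candidate record).
#' @export
classifySsrCluster <- function(cluster, lines, minReadsPerLine = 1L) {
  obs <- cluster@observations
  obs <- obs[obs$type == "SSR" & !is.na(obs$value), , drop = FALSE]
  motifs <- unique(obs$motif)
  if (length(motifs) > 1L)
    return(.candidateRow(cluster, "SSR", "conflicted", NA, "", "", lines))
  o1 <- obs$value[obs$line %in% lines[1L]]
  o2 <- obs$value[obs$line %in% lines[2L]]
  have1 <- length(o1) >= minReadsPerLine
  have2 <- length(o2) >= minReadsPerLine
  if (!have1 && !have2)
    return(.candidateRow(cluster, "SSR", "conflicted", motifs, o1, o2, lines))
  if (xor(have1, have2))
    return(.candidateRow(cluster, "SSR", "single_line", motifs, o1, o2, lines))
  c1 <- .majorityValue(o1)
  c2 <- .majorityValue(o2)
  if (is.na(c1) || is.na(c2))
    return(.candidateRow(cluster, "SSR", "conflicted", motifs, o1, o2, lines))
  cls <- if (c1 != c2) "polymorphic" else "monomorphic"
  .candidateRow(cluster, "SSR", cls, motifs, o1, o2, lines)
}

#' Detect a transposon in a read
#'
#' Local alignment of the read against the transposon consensus; the
#' read is called TE-containing when the alignment spans at least
#' `minLen` columns at `minIdentity` or better. Both strands are tried.
#' The returned annotation records the matched read interval and the
#' genomic flanks that remain on either side. Thresholds default to 30 bp
#' at 80% identity, loose enough to tolerate terminal-inverted-repeat
#' divergence of MITE family members.
#'
#' @param read one read sequence (character).
#' @param teConsensus transposon consensus sequence (character).
#' @param minLen minimum aligned columns.
#' @param minIdentity minimum identity over the aligned region.
#' @return `NULL` when no TE is found, otherwise a list with `start`,
#'   `end` (0-based half-open matched interval in the read), `identity`,
#'   `alignedCols`, `strand`, and `flanks` (list of `left`/`right`
#'   0-based intervals, absent sides dropped).
#' @export
detectTe <- function(read, teConsensus, minLen = 30L, minIdentity = 0.80) {
  stopifnot(nchar(teConsensus) > 0L)
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL
  for (strand in c("+", "-")) {
    cons <- if (strand == "+") teConsensus else .revcomp(teConsensus)
    al <- Biostrings::pairwiseAlignment(read, cons, type = "local",
                                        substitutionMatrix = sub,
                                        gapOpening = 4, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::pattern(al)))
    if (cols == 0L) next
    ident <- Biostrings::nmatch(al) / cols
    if (cols >= minLen && ident >= minIdentity &&
        (is.null(best) || ident * cols > best$identity * best$alignedCols)) {
      p <- Biostrings::pattern(al)
      best <- list(start = Biostrings::start(p) - 1L,
                   end = Biostrings::end(p),
                   identity = ident, alignedCols = cols, strand = strand)
    }
  }
  if (is.null(best)) return(NULL)
  fl <- list()
  if (best$start > 0L) fl$left <- c(0L, best$start)
  if (best$end < nchar(read)) fl$right <- c(best$end, nchar(read))
  best$flanks <- fl
  best
}

#' Annotate reads with transposon junctions
#'
#' Runs [detectTe()] over a read set and returns the annotation table
#' used by [clusterReads()]; undetected reads get no annotation.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @inheritParams detectTe
#' @return annotation data.frame (`read`, `start`, `end`, `type = "TE"`,
#'   `motif = NA`, `value = 1`).
#' @export
teAnnotations <- function(reads, teConsensus, minLen = 30L,
                          minIdentity = 0.80) {
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  rows <- lapply(names(reads), function(id) {
    hit <- detectTe(reads[[id]], teConsensus, minLen, minIdentity)
    if (is.null(hit)) return(NULL)
    data.frame(read = id, start = hit$start, end = hit$end, type = "TE",
               motif = NA_character_, value = 1)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(read = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      motif = character(0), value = numeric(0)))
  do.call(rbind, rows)
}

#' Classify a transposon-junction cluster
#'
#' A cluster of TE-containing reads is a polymorphic (cultivar-specific
#' insertion) candidate iff its members come from exactly one line, and
#' monomorphic when both lines are present.
#'
#' @param cluster a [SeqCluster-class] of junction reads.
#' @param lines character pair naming the two lines.
#' @return one-row data.frame (a marker candidate record).
#' @export
classifyTeCluster <- function(cluster, lines) {
  obs <- cluster@observations
  obs <- obs[obs$type == "TE", , drop = FALSE]
  if (!nrow(obs)) stop("cluster has no TE-containing members")
  present <- lines %in% obs$line
  cls <- if (all(present)) "monomorphic"
         else if (any(present)) "polymorphic"
         else "conflicted"
  .candidateRow(cluster, "TE", cls,
                NA, obs$value[obs$line %in% lines[1L]],
                obs$value[obs$line %in% lines[2L]], lines)
}

#' Classify every cluster of a run
#'
#' Applies the SSR and/or TE classifier to each cluster according to the
#' feature types observed in it; a cluster carrying both feature types
#' yields two candidate records with distinct ids.
#'
#' @param clusters list of [SeqCluster-class].
#' @param lines character pair naming the two lines.
#' @param minReadsPerLine passed to [classifySsrCluster()].
#' @return data.frame of marker candidates, one row per (cluster,
#'   feature type).
#' @export
screenClusters <- function(clusters, lines, minReadsPerLine = 1L) {
  rows <- lapply(clusters, function(cl) {
    types <- unique(cl@observations$type)
    out <- list()
    if ("SSR" %in% types)
      out <- c(out, list(classifySsrCluster(cl, lines, minReadsPerLine)))
    if ("TE" %in% types)
      out <- c(out, list(classifyTeCluster(cl, lines)))
    do.call(rbind, out)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Marker screening summary table
#'
#' Counts and percentages per marker type and class, in the layout of a
#' marker-development bookkeeping table. Percentages are
#' `100 * count / total` rounded half-up to one decimal; conflicted
#' clusters count toward the total but have no percentage column of
#' their own interest beyond the count.
#'
#' @param candidates data.frame from [screenClusters()] (or the single
#'   classifiers).
#' @return data.frame, one row per marker type.
#' @export
screenReport <- function(candidates) {
  types <- sort(unique(candidates$marker_type))
  rows <- lapply(types, function(tp) {
    d <- candidates[candidates$marker_type == tp, , drop = FALSE]
    tot <- nrow(d)
    cnt <- function(cl) sum(d$class == cl)
    data.frame(marker_type = tp, n_total = tot,
               n_polymorphic = cnt("polymorphic"),
               pct_polymorphic = percentHalfUp(cnt("polymorphic"), tot),
               n_monomorphic = cnt("monomorphic"),
               pct_monomorphic = percentHalfUp(cnt("monomorphic"), tot),
               n_single_line = cnt("single_line"),
               pct_single_line = percentHalfUp(cnt("single_line"), tot),
               n_conflicted = cnt("conflicted"))
  })
  do.call(rbind, rows)
}
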