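# SSR tract detection and motif canonicalization.

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i)
    paste0(substring(m, i, k), substring(m, 1L, i - 1L)), character(1))
}

.isPrimitive <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && m == strrep(substring(m, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

#' Canonical class of a repeat motif
#'
#' Maps every rotation and reverse complement of a motif to one class
#' representative, so that e.g. TC, CT, GA and AG all tally as the (CT)n
#' class and AC, CA, GT and TG as (AC)n. The representative is the
#' lexicographically smallest rotation taken on the pyrimidine-richer
#' strand (ties consider both strands), which reproduces the conventional
#' microsatellite class names (AC)n and (CT)n. Idempotent, and invariant
#' under rotation and reverse complement of the argument.
#'
#' @param motif character vector of DNA motifs, each of length 2-6,
#'   ACGT-only and primitive (not itself a repetition of a shorter unit;
#'   e.g. "ATAT" is rejected).
#' @return character vector of canonical class strings.
#' @examples
#' canonicalMotif(c("TC", "GA", "AC"))
#' @export
canonicalMotif <- function(motif) {
  vapply(motif, function(m) {
    if (is.na(m) || nchar(m) < 2L || nchar(m) > 6L)
      stop("motif length must be 2-6: '", m, "'")
    if (grepl("[^ACGT]", m))
      stop("motif must contain only ACGT: '", m, "'")
    if (!.isPrimitive(m))
      stop("motif is not primitive (repeats a shorter unit): '", m, "'")
    rc <- .revcomp(m)
    npyr <- function(s) nchar(gsub("[^CT]", "", s))
    pool <- if (npyr(m) > npyr(rc)) .rotations(m)
            else if (npyr(rc) > npyr(m)) .rotations(rc)
            else c(.rotations(m), .rotations(rc))
    min(pool)
  }, character(1), USE.NAMES = FALSE)
}

.findTracts1 <- function(s, minRepeats) {
  s <- toupper(s)
  n <- nchar(s)
  y <- utf8ToInt(s)
  # positions outside ACGT (incl. N) get unique sentinels so they never match
  bad <- !(y %in% utf8ToInt("ACGT"))
  if (any(bad)) y[bad] <- -seq_len(sum(bad))
  hits <- list()
  for (k in as.integer(names(minRepeats))) {
    thr <- minRepeats[[as.character(k)]]
    if (n < k * thr) next
    eq <- y[seq_len(n - k)] == y[seq.int(k + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths + k >= k * thr)) {
      i <- starts[ri]
      L <- r$lengths[ri] + k          # length of the perfectly periodic region
      count <- L %/% k
      if (count < thr) next
      unit <- substring(s, i, i + k - 1L)
      if (!.isPrimitive(unit)) next   # picked up at the true (shorter) period
      hits[[length(hits) + 1L]] <- c(start = i - 1L, k = k, count = count)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), observed_motif = character(0),
                      repeat_count = integer(0), tract_len = integer(0)))
  h <- do.call(rbind, hits)
  d <- data.frame(start = h[, "start"], k = h[, "k"], count = h[, "count"])
  d$tract_len <- d$count * d$k
  d$end <- d$start + d$tract_len
  # overlap resolution: longer tract wins, ties to the smaller start
  d <- d[order(-d$tract_len, d$start), , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    ov <- keep & d$start < d$end[i] & d$end > d$start[i]
    keep[i] <- !any(ov)
  }
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  d$observed_motif <- substring(s, d$start + 1L, d$start + d$k)
  d$motif <- canonicalMotif(d$observed_motif)
  data.frame(start = d$start, end = d$end, motif = d$motif,
             observed_motif = d$observed_motif, repeat_count = d$count,
             tract_len = d$tract_len)
}

#' Find perfect SSR tracts
#'
#' Reports every maximal perfect repeat run with a primitive unit of 2-4
#' bases and at least the per-unit-length minimum number of copies.
#' Coordinates are 0-based half-open. A run reported under several phases
#' or unit lengths is merged to a single tract; when two distinct maximal
#' tracts overlap, the longer one wins (ties to the smaller start).
#' Partial trailing copies are trimmed, so `tract_len` is always
#' `repeat_count * nchar(observed_motif)`. `N` never matches.
#'
#' Only perfect repeats are reported; an interrupted repeat splits at the
#' mismatch. Mononucleotide runs and units of 5-6 bases are not scanned.
#'
#' @param x sequences: a named character vector or a
#'   [Biostrings::DNAStringSet].
#' @param minRepeats named integer vector mapping unit length to the
#'   minimum repeat count (defaults: di 6, tri 5, tetra 5).
#' @return data.frame with columns `seqid`, `start`, `end`, `motif`
#'   (canonical class), `observed_motif` (as-read phase), `repeat_count`,
#'   `tract_len`, sorted by sequence then start.
#' @examples
#' findTracts(c(r1 = "ACACACACACACACACACACACAC"))
#' @export
findTracts <- function(x, minRepeats = c("2" = 6L, "3" = 5L, "4" = 5L)) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  stopifnot(all(names(minRepeats) %in% as.character(2:4)))
  out <- lapply(names(x), function(id) {
    d <- .findTracts1(x[[id]], minRepeats)
    if (nrow(d)) cbind(seqid = id, d) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      observed_motif = character(0),
                      repeat_count = integer(0), tract_len = integer(0)))
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Tally canonical motif classes
#'
#' @param tracts data.frame from [findTracts()] (or anything with a
#'   `motif` column of canonical classes).
#' @return data.frame with columns `motif`, `count`, `fraction`, ordered
#'   by descending count then lexicographically. Fractions sum to 1.
#' @export
tallyMotifClasses <- function(tracts) {
  if (!nrow(tracts))
    return(data.frame(motif = character(0), count = integer(0),
                      fraction = numeric(0)))
  tab <- table(tracts$motif)
  d <- data.frame(motif = names(tab), count = as.integer(tab))
  d <- d[order(-d$count, d$motif), , drop = FALSE]
  d$fraction <- d$count / sum(d$count)
  rownames(d) <- NULL
  d
}
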