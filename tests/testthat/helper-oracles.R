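# Independent oracles and small fixtures, deliberately implemented
# without reusing package internals.

rcT <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Brute-force SSR scanner: enumerates every start and unit length,
# extends whole copies, keeps leftmost-phase maximal runs above the
# threshold, then resolves overlaps longest-first (ties to the smaller
# start) -- the same contract as findTracts, derived independently.
bruteTracts <- function(s, minRepeats = c("2" = 6L, "3" = 5L, "4" = 5L)) {
  n <- nchar(s)
  cand <- list()
  for (k in 2:4) {
    thr <- minRepeats[[as.character(k)]]
    if (n < k * thr) next
    for (st in seq_len(n - k * thr + 1L)) {
      unit <- substr(s, st, st + k - 1L)
      if (grepl("[^ACGT]", unit)) next
      prim <- TRUE
      for (d in seq_len(k - 1L))
        if (k %% d == 0L && unit == strrep(substr(unit, 1L, d), k / d))
          prim <- FALSE
      if (!prim) next
      if (st > k && substr(s, st - k, st - 1L) == unit) next
      cnt <- 1L
      while (st + (cnt + 1L) * k - 1L <= n &&
             substr(s, st + cnt * k, st + (cnt + 1L) * k - 1L) == unit)
        cnt <- cnt + 1L
      if (cnt < thr) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = st - 1L, end = st - 1L + cnt * k,
                   count = cnt, unit = unit)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      count = integer(0), unit = character(0)))
  d <- do.call(rbind, cand)
  d$len <- d$end - d$start
  d <- d[order(-d$len, d$start), , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d)))
    keep[i] <- !any(keep & d$start < d$end[i] & d$end > d$start[i])
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$start), c("start", "end", "count", "unit")]
  rownames(d) <- NULL
  d
}

# F2 two-locus joint class probabilities in coupling phase, written as
# the closed-form table (t = (1-r)/2 parental, s = r/2 recombinant
# gamete frequencies), vectorized over r.
f2ClassProbVec <- function(rs, set1, set2) {
  t <- (1 - rs) / 2
  s <- rs / 2
  P <- list(`11` = t^2,        `12` = 2 * t * s, `13` = s^2,
            `21` = 2 * t * s,  `22` = 2 * t^2 + 2 * s^2, `23` = 2 * t * s,
            `31` = s^2,        `32` = 2 * t * s, `33` = t^2)
  out <- 0
  for (g1 in set1) for (g2 in set2) out <- out + P[[paste0(g1, g2)]]
  out
}

# Grid-search maximum-likelihood recombination fraction: a 2001-point
# grid over [0, 0.5], refined by a second 2001-point grid inside the
# winning interval so the oracle's own quantization is far below the
# comparison tolerance.
gridRfOracle <- function(col1, col2) {
  sets <- list(a = 1, h = 2, b = 3, c = c(2, 3), d = c(1, 2))
  keep <- col1 != "-" & col2 != "-"
  tab <- table(paste0(col1[keep], col2[keep]))
  llv <- function(rs) {
    tot <- 0
    for (cc in names(tab)) {
      p <- f2ClassProbVec(rs, sets[[substr(cc, 1, 1)]],
                          sets[[substr(cc, 2, 2)]])
      tot <- tot + tab[[cc]] * log(p)
    }
    tot
  }
  rs1 <- seq(0, 0.5, length.out = 2001)
  v1 <- llv(rs1)
  r1 <- rs1[which.max(v1)]
  step <- 0.5 / 2000
  rs2 <- seq(max(0, r1 - step), min(0.5, r1 + step), length.out = 2001)
  v2 <- llv(rs2)
  list(rf = rs2[which.max(v2)], ll = max(v2),
       lod = (max(v2) - llv(0.5)) / log(10), llFun = llv)
}

# Nearest-neighbor melting temperatures for fixed probe sequences,
# computed once with an independent implementation of the unified
# parameter set (Biopython MeltingTemp.Tm_NN, DNA_NN3, Na = 50 mM,
# strand concentration C/4 = 62.5 nM, entropic salt correction).
TM_ORACLE <- c(
  ACGTACGTACGTACGTACGT = 55.222,
  AGCGGATAACAATTTCACACAGGA = 56.7151,
  GTAAAACGACGGCCAGT = 51.6742,
  ATCGATCGATCGATCGATCG = 53.9255,
  GCGCGCATATGCGCGCATAT = 61.7785,
  TTTTTTTTTTAAAAAAAAAA = 37.1756,
  CAGGAAACAGCTATGACCAT = 51.529
)

# evenly spaced truth map for simulation tests
makeTruthMap <- function(nGroups = 2L, lociPerGroup = 8L, spacing = 10) {
  data.frame(group = rep(paste0("chr", seq_len(nGroups)),
                         each = lociPerGroup),
             locus = sprintf("m%03d", seq_len(nGroups * lociPerGroup)),
             position_cM = rep(seq(0, by = spacing,
                                   length.out = lociPerGroup), nGroups))
}

# all permutations of a small vector (for exhaustive order checks)
allPerms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# a cluster object built directly, for classifier unit tests
makeCluster <- function(obs1, obs2, motif = "AC", type = "SSR",
                        lines = c("line1", "line2"), motifs = NULL) {
  vals <- c(obs1, obs2)
  line <- c(rep(lines[1L], length(obs1)), rep(lines[2L], length(obs2)))
  reads <- if (length(vals)) paste0(line, "|locus|", seq_along(vals))
           else character(0)
  if (is.null(motifs)) motifs <- rep(motif, length(vals))
  new("SeqCluster", id = "cluster_0001",
      members = data.frame(read = reads, line = line,
                           orientation = rep("+", length(reads))),
      observations = data.frame(read = reads, line = line,
                                type = rep(type, length(reads)),
                                motif = if (type == "TE")
                                          rep(NA_character_, length(reads))
                                        else motifs,
                                value = as.numeric(vals)),
      repRead = if (length(reads)) reads[1L] else character(0),
      repSeq = paste0(strrep("GATTACAGATTACAGATTACA", 4L),
                      strrep(motif, 10L),
                      strrep("TTGACCATTGACCATTGACCA", 4L)),
      repFeature = c(84, 84 + nchar(motif) * 10))
}
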