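# PCR primer picking on candidate flanks, with a nearest-neighbor
# melting-temperature model.

# Unified nearest-neighbor parameters (Allawi & SantaLucia 1997 set):
# dH in kcal/mol, dS in cal/(mol K), 5'->3' dinucleotide steps with
# complementary steps folded in.
.NN_H <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
.NN_S <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameters, with terminal A/T and G/C initiation terms,
#' an entropic monovalent-salt correction of `0.368 (N-1) ln[Na+]`, and
#' the non-self-complementary concentration factor `R ln(C/4)`. The
#' conditions are fixed as part of the contract so values are
#' reproducible: 50 mM monovalent cation, 250 nM primer. By symmetry of
#' the parameter set, a sequence and its reverse complement share a Tm.
#'
#' @param seq character vector of ACGT sequences of length 10-36.
#' @return melting temperatures in degrees Celsius.
#' @examples
#' meltingTemp("AGCGGATAACAATTTCACACAGGA")
#' @export
meltingTemp <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 10L || n > 36L)
      stop("sequence length must be 10-36 bases, got ", n)
    if (grepl("[^ACGT]", s))
      stop("ambiguity codes are not supported: '", s, "'")
    b <- strsplit(s, "")[[1L]]
    steps <- paste0(b[-n], b[-1L])
    dH <- sum(.NN_H[steps])
    dS <- sum(.NN_S[steps])
    for (t in b[c(1L, n)]) {
      if (t %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
      else                    { dH <- dH + 0.1; dS <- dS - 2.8 }
    }
    na <- 0.05                     # 50 mM monovalent
    ct <- 250e-9                   # 250 nM primer
    dS <- dS + 0.368 * (n - 1L) * log(na)
    1000 * dH / (dS + 1.9872 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

.gcFraction <- function(s) {
  nchar(gsub("[^GC]", "", s)) / nchar(s)
}

# TRUE when a 3' suffix of `primer` longer than maxLen has its reverse
# complement somewhere in `other` (exact-complement check, not
# thermodynamic)
.comp3p <- function(primer, other, maxLen = 4L) {
  n <- nchar(primer)
  for (L in seq.int(maxLen + 1L, min(n, 12L))) {
    sfx <- substring(primer, n - L + 1L, n)
    if (grepl(.revcomp(sfx), other, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

.windowTable <- function(template, lo, hi, lenRange, source) {
  if (hi - lo + 1L < lenRange[1L])
    return(data.frame(start = integer(0), len = integer(0),
                      seq = character(0), source = character(0)))
  rows <- list()
  for (L in seq.int(lenRange[1L], lenRange[2L])) {
    starts <- seq.int(lo, hi - L + 1L)
    if (!length(starts) || starts[1L] > hi - L + 1L) next
    rows[[length(rows) + 1L]] <-
      data.frame(start = starts, len = L,
                 seq = substring(template, starts + 1L, starts + L),
                 source = source)
  }
  do.call(rbind, rows)
}

#' Design ranked PCR primer pairs around a target feature
#'
#' Enumerates candidate left-primer windows in the left flank and
#' right-primer windows in the right flank (taken as the reverse
#' complement of the template window), filters each on melting
#' temperature, GC fraction, homopolymer runs and 3'-end
#' self-complementarity, pairs them under the product-length range with a
#' 3'-end cross-complementarity check, and ranks pairs by a penalty of
#' weighted deviations from the optima. Neither primer may overlap the
#' target interval. For a transposon candidate whose flank is too short
#' to host a primer, `allowInternal = TRUE` lets the deficient side's
#' primer be drawn from the transposon interior instead (the classic
#' fallback when one junction flank is missing).
#'
#' Numeric defaults follow common practice for SSR genotyping assays:
#' window 18-27 bases, Tm 57-63 degC (optimum 60), GC 0.30-0.70, no
#' homopolymer of 5+, 3' complementarity at most 4 bases, product 80-400
#' bases. Ranking is total and deterministic: penalty, then leftmost left
#' primer, then shortest product.
#'
#' @param template candidate template sequence (character).
#' @param targetStart,targetEnd 0-based half-open target feature interval.
#' @param lenRange,tmRange,gcRange,productRange filter intervals.
#' @param maxHomopolymer longest allowed single-base run.
#' @param max3pComp longest allowed 3'-end exact complementarity.
#' @param optLen,optTm,optGc penalty optima.
#' @param allowInternal allow primers inside the target interval when the
#'   corresponding flank is too short (TE candidates).
#' @param maxPerSide cap on singles kept per side (best by single-primer
#'   penalty) before pairing.
#' @return data.frame of primer pairs ranked best-first, with sequences,
#'   0-based start positions, Tm, GC, product length, penalty and the
#'   source (`flank` or `te_interior`) of each primer. When no pair is
#'   feasible the result has zero rows and an attribute `rejections`
#'   tallying per-filter rejection counts.
#' @export
designPrimers <- function(template, targetStart, targetEnd,
                          lenRange = c(18L, 27L), tmRange = c(57, 63),
                          gcRange = c(0.30, 0.70), productRange = c(80L, 400L),
                          maxHomopolymer = 4L, max3pComp = 4L,
                          optLen = 20L, optTm = 60, optGc = 0.5,
                          allowInternal = FALSE, maxPerSide = 150L) {
  n <- nchar(template)
  stopifnot(n >= 60L, targetStart >= 0L, targetEnd >= targetStart,
            targetEnd <= n)
  rejections <- c(tm = 0L, gc = 0L, homopolymer = 0L, self3p = 0L,
                  product_len = 0L, cross3p = 0L)

  left <- .windowTable(template, 0L, targetStart - 1L, lenRange, "flank")
  right <- .windowTable(template, targetEnd, n - 1L, lenRange, "flank")
  if (allowInternal && targetEnd > targetStart) {
    if (!nrow(left))
      left <- .windowTable(template, targetStart, targetEnd - 1L, lenRange,
                           "te_interior")
    if (!nrow(right))
      right <- .windowTable(template, targetStart, targetEnd - 1L, lenRange,
                            "te_interior")
  }
  right$seq <- if (nrow(right)) .revcomp(right$seq) else right$seq

  filterSide <- function(w) {
    if (!nrow(w)) return(w)
    w$tm <- meltingTemp(w$seq)
    ok <- w$tm >= tmRange[1L] & w$tm <= tmRange[2L]
    rejections["tm"] <<- rejections[["tm"]] + sum(!ok)
    w <- w[ok, , drop = FALSE]
    if (!nrow(w)) return(w)
    w$gc <- .gcFraction(w$seq)
    ok <- w$gc >= gcRange[1L] & w$gc <= gcRange[2L]
    rejections["gc"] <<- rejections[["gc"]] + sum(!ok)
    w <- w[ok, , drop = FALSE]
    if (!nrow(w)) return(w)
    homo <- paste0(sprintf("%s{%d}", c("A", "C", "G", "T"),
                           maxHomopolymer + 1L), collapse = "|")
    ok <- !grepl(homo, w$seq)
    rejections["homopolymer"] <<- rejections[["homopolymer"]] + sum(!ok)
    w <- w[ok, , drop = FALSE]
    if (!nrow(w)) return(w)
    ok <- !vapply(w$seq, function(s) .comp3p(s, s, max3pComp), logical(1))
    rejections["self3p"] <<- rejections[["self3p"]] + sum(!ok)
    w <- w[ok, , drop = FALSE]
    if (nrow(w)) {
      w$penalty1 <- abs(w$len - optLen) + abs(w$tm - optTm) +
        10 * abs(w$gc - optGc)
      w <- w[order(w$penalty1), , drop = FALSE]
      w <- head(w, maxPerSide)
    }
    w
  }
  left <- filterSide(left)
  right <- filterSide(right)

  empty <- data.frame(left_seq = character(0), right_seq = character(0),
                      left_start = integer(0), right_start = integer(0),
                      left_len = integer(0), right_len = integer(0),
                      left_tm = numeric(0), right_tm = numeric(0),
                      left_gc = numeric(0), right_gc = numeric(0),
                      left_source = character(0), right_source = character(0),
                      product_len = integer(0), penalty = numeric(0))
  if (!nrow(left) || !nrow(right)) {
    attr(empty, "rejections") <- rejections
    return(empty)
  }

  g <- expand.grid(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
  prod_len <- (right$start[g$ri] + right$len[g$ri]) - left$start[g$li]
  ok <- prod_len >= productRange[1L] & prod_len <= productRange[2L] &
    prod_len > 0L
  rejections["product_len"] <- rejections[["product_len"]] + sum(!ok)
  g <- g[ok, , drop = FALSE]
  prod_len <- prod_len[ok]
  if (!nrow(g)) {
    attr(empty, "rejections") <- rejections
    return(empty)
  }
  cross <- mapply(function(li, ri) {
    .comp3p(left$seq[li], right$seq[ri], max3pComp) ||
      .comp3p(right$seq[ri], left$seq[li], max3pComp)
  }, g$li, g$ri)
  rejections["cross3p"] <- rejections[["cross3p"]] + sum(cross)
  g <- g[!cross, , drop = FALSE]
  prod_len <- prod_len[!cross]
  if (!nrow(g)) {
    attr(empty, "rejections") <- rejections
    return(empty)
  }
  out <- data.frame(
    left_seq = left$seq[g$li], right_seq = right$seq[g$ri],
    left_start = left$start[g$li], right_start = right$start[g$ri],
    left_len = left$len[g$li], right_len = right$len[g$ri],
    left_tm = left$tm[g$li], right_tm = right$tm[g$ri],
    left_gc = left$gc[g$li], right_gc = right$gc[g$ri],
    left_source = left$source[g$li], right_source = right$source[g$ri],
    product_len = prod_len)
  out$penalty <- abs(out$left_len - optLen) + abs(out$right_len - optLen) +
    abs(out$left_tm - optTm) + abs(out$right_tm - optTm) +
    10 * (abs(out$left_gc - optGc) + abs(out$right_gc - optGc)) +
    abs(out$left_tm - out$right_tm)
  out <- out[order(out$penalty, out$left_start, out$product_len), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}
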