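# F2 linkage mapping: segregation tests, two-point EM recombination
# fractions, LOD grouping, SARF/2-opt ordering, Haldane distances.

#' Haldane mapping function
#'
#' Map distance under the assumption of no crossover interference:
#' `d = -50 ln(1 - 2r)` centiMorgans. `r = 0.5` (unlinked) maps to an
#' infinite distance, signaled explicitly with a warning.
#'
#' @param r recombination fraction(s) in \[0, 0.5\].
#' @return distance in cM.
#' @examples
#' haldaneCM(0.25)  # 34.657
#' @export
haldaneCM <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  if (any(r == 0.5)) warning("r = 0.5 corresponds to an infinite distance")
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane mapping function
#'
#' @param d distance(s) in cM, non-negative.
#' @return recombination fraction `(1 - exp(-d/50)) / 2`.
#' @export
haldaneR <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  (1 - exp(-d / 50)) / 2
}

.codeSets <- list(a = 0L, h = 1L, b = 2L, c = c(1L, 2L), d = c(0L, 1L))

#' Segregation chi-square test for one locus
#'
#' Codominant loci are tested against the Mendelian F2 expectation 1:2:1
#' (df = 2), dominant loci against 3:1 (df = 1), without continuity
#' correction. The p-value is the upper tail of the chi-square
#' distribution.
#'
#' @param column character vector of genotype codes for one locus.
#' @return list with `chi2`, `p`, `df`, `type` and the observed `counts`.
#' @examples
#' segregationChisq(rep(c("a", "h", "h", "b"), 25))
#' @export
segregationChisq <- function(column) {
  obs <- column[column != "-"]
  if (length(obs) < 2L)
    stop("need at least 2 non-missing observations")
  type <- locusType(column)
  if (type == "codominant") {
    counts <- c(a = sum(obs == "a"), h = sum(obs == "h"), b = sum(obs == "b"))
    expd <- length(obs) * c(1, 2, 1) / 4
    df <- 2L
  } else if (type == "dominant_a") {
    counts <- c(a = sum(obs == "a"), c = sum(obs == "c"))
    expd <- length(obs) * c(1, 3) / 4
    df <- 1L
  } else {
    counts <- c(b = sum(obs == "b"), d = sum(obs == "d"))
    expd <- length(obs) * c(1, 3) / 4
    df <- 1L
  }
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE), df = df,
       type = type, counts = counts)
}

# 16 ordered gamete-pair states for a two-locus F2 (coupling-phase F1):
# each gamete carries an allele (0 = first parent, 1 = second) at each
# locus; a gamete is recombinant when its two alleles differ.
.gameteStates <- local({
  g <- expand.grid(x1 = 0:1, y1 = 0:1, x2 = 0:1, y2 = 0:1)
  list(g1 = g$x1 + g$x2,                 # genotype at locus 1 (0/1/2)
       g2 = g$y1 + g$y2,                 # genotype at locus 2
       rec = (g$x1 != g$y1) + (g$x2 != g$y2),
       same = cbind(g$x1 == g$y1, g$x2 == g$y2))
})

.statePrior <- function(r) {
  s <- .gameteStates$same
  0.25 * ifelse(s[, 1L], 1 - r, r) * ifelse(s[, 2L], 1 - r, r)
}

#' Two-point recombination fraction by EM
#'
#' Maximizes the multinomial likelihood of the observed joint genotype
#' classes over the recombination fraction `r`, treating the ordered
#' gamete pair of each individual as the latent variable (which handles
#' the coupling/repulsion mixture inside the double-heterozygote class
#' and all dominant collapsings uniformly). Individuals missing either
#' locus are dropped. The E step imputes the expected number of
#' recombinant gametes, the M step divides by `2n`; iteration stops at
#' `|delta r| < 1e-6`, with `r` confined to \[0, 0.5\]. The LOD score is
#' `log10 L(r-hat) - log10 L(0.5)`.
#'
#' Pairs of dominant loci in repulsion configuration (`a/c` against
#' `b/d`) carry very little linkage information in an F2 and are flagged
#' `repulsionDD = TRUE`.
#'
#' @param col1,col2 genotype code vectors for the two loci.
#' @param tol EM convergence tolerance on `r`.
#' @return list with `rf`, `lod`, `n` (informative individuals), the two
#'   locus types and the `repulsionDD` flag.
#' @export
estimateRfF2 <- function(col1, col2, tol = 1e-6) {
  keep <- col1 != "-" & col2 != "-"
  c1 <- col1[keep]; c2 <- col2[keep]
  n <- length(c1)
  if (n < 10L) stop("need >= 10 individuals non-missing at both loci")
  if (length(unique(c1)) < 2L || length(unique(c2)) < 2L)
    stop("monomorphic locus: recombination fraction is not estimable")
  t1 <- locusType(col1); t2 <- locusType(col2)
  repulsionDD <- (t1 == "dominant_a" && t2 == "dominant_b") ||
    (t1 == "dominant_b" && t2 == "dominant_a")

  cls <- paste0(c1, c2)
  counts <- table(cls)
  # compatibility mask: observed class -> set of gamete-pair states
  masks <- lapply(names(counts), function(cc) {
    s1 <- .codeSets[[substring(cc, 1L, 1L)]]
    s2 <- .codeSets[[substring(cc, 2L, 2L)]]
    .gameteStates$g1 %in% s1 & .gameteStates$g2 %in% s2
  })
  cnt <- as.numeric(counts)

  loglik <- function(r) {
    pr <- .statePrior(r)
    sum(cnt * log(vapply(masks, function(m) sum(pr[m]), numeric(1))))
  }
  r <- 0.25
  for (it in seq_len(2000L)) {
    pr <- .statePrior(r)
    erec <- vapply(masks, function(m) {
      w <- pr[m]
      sum(w * .gameteStates$rec[m]) / sum(w)
    }, numeric(1))
    rNew <- min(max(sum(cnt * erec) / (2 * n), 0), 0.5)
    if (abs(rNew - r) < tol) { r <- rNew; break }
    r <- rNew
  }
  lod <- (loglik(r) - loglik(0.5)) / log(10)
  list(rf = r, lod = max(lod, 0), n = n, type1 = t1, type2 = t2,
       repulsionDD = repulsionDD)
}

#' All pairwise two-point estimates
#'
#' Runs [estimateRfF2()] over every locus pair of a genotype matrix.
#' Pairs that are not estimable (monomorphic locus, too few informative
#' individuals) are recorded with `NA` and the reason.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param minInformative minimum individuals non-missing at both loci.
#' @return data.frame with `locus1`, `locus2`, `rf`, `lod`, `n`,
#'   `repulsionDD`, `note`.
#' @export
pairwiseRf <- function(geno, minInformative = 10L) {
  m <- genoCodes(geno)
  loci <- colnames(m)
  if (length(loci) < 2L) stop("need at least two loci")
  pr <- combn(length(loci), 2L)
  rows <- lapply(seq_len(ncol(pr)), function(pi) {
    i <- pr[1L, pi]; j <- pr[2L, pi]
    res <- tryCatch(estimateRfF2(m[, i], m[, j]),
                    error = function(e) conditionMessage(e))
    if (is.character(res))
      data.frame(locus1 = loci[i], locus2 = loci[j], rf = NA_real_,
                 lod = NA_real_, n = NA_integer_, repulsionDD = NA,
                 note = res)
    else
      data.frame(locus1 = loci[i], locus2 = loci[j], rf = res$rf,
                 lod = res$lod, n = res$n, repulsionDD = res$repulsionDD,
                 note = "")
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Group loci by pairwise linkage
#'
#' Single-linkage connected components of the graph with an edge between
#' two loci iff their two-point LOD is at least `lodThreshold` and the
#' recombination fraction at most `maxRf`.
#'
#' @param pairs data.frame from [pairwiseRf()].
#' @param lodThreshold LOD threshold (> 0); grouping is conventionally
#'   swept over 4-10, with 4 as the permissive default.
#' @param maxRf recombination-fraction ceiling for an edge.
#' @param loci optional full locus set (so unlinked loci appear as
#'   singleton groups); defaults to the loci present in `pairs`.
#' @return list of character vectors (groups), largest first, loci
#'   sorted within each group.
#' @export
groupLoci <- function(pairs, lodThreshold = 4, maxRf = 0.30, loci = NULL) {
  stopifnot(lodThreshold > 0)
  if (is.null(loci)) loci <- sort(unique(c(pairs$locus1, pairs$locus2)))
  idx <- seq_along(loci)
  names(idx) <- loci
  parent <- idx
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sel <- !is.na(pairs$rf) & pairs$lod >= lodThreshold & pairs$rf <= maxRf
  for (k in which(sel)) {
    ri <- findRoot(idx[[pairs$locus1[k]]])
    rj <- findRoot(idx[[pairs$locus2[k]]])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- split(loci, vapply(idx, findRoot, numeric(1)))
  comp <- lapply(comp, sort)
  comp[order(-lengths(comp),
             vapply(comp, `[`, character(1), 1L))]
}

#' Grouping sweep over LOD thresholds
#'
#' @inheritParams groupLoci
#' @param thresholds LOD thresholds to sweep (default 4 through 10).
#' @return named list of partitions, one per threshold. Raising the
#'   threshold can only refine the partition, never merge groups.
#' @export
sweepGroupings <- function(pairs, thresholds = 4:10, maxRf = 0.30,
                           loci = NULL) {
  out <- lapply(thresholds, function(th)
    groupLoci(pairs, th, maxRf, loci))
  names(out) <- as.character(thresholds)
  out
}

.sarf <- function(ord, rfm) {
  sum(rfm[cbind(ord[-length(ord)], ord[-1L])])
}

#' Order the loci of one linkage group
#'
#' Builds an initial order by greedy chain extension from the locus pair
#' with the smallest recombination fraction, appending at whichever chain
#' end adds the least, then refines by 2-opt segment reversals until the
#' SARF (sum of adjacent recombination fractions) reaches a local
#' optimum. Positions are cumulative Haldane distances over adjacent
#' estimates. Orientation is normalized so the lexicographically smaller
#' terminal locus comes first. An unestimable pair is treated as
#' unlinked (rf 0.5) for the objective; a group none of whose loci can
#' be chained through finite estimates is rejected.
#'
#' @param loci character vector, the group's loci (length >= 2).
#' @param pairs data.frame from [pairwiseRf()].
#' @return data.frame with `locus` and `position_cM` in map order.
#' @export
orderGroup <- function(loci, pairs) {
  stopifnot(length(loci) >= 2L)
  rfm <- matrix(0.5, length(loci), length(loci),
                dimnames = list(loci, loci))
  sel <- pairs$locus1 %in% loci & pairs$locus2 %in% loci & !is.na(pairs$rf)
  for (k in which(sel)) {
    rfm[pairs$locus1[k], pairs$locus2[k]] <- pairs$rf[k]
    rfm[pairs$locus2[k], pairs$locus1[k]] <- pairs$rf[k]
  }
  diag(rfm) <- 0
  # reject a group that cannot be chained through finite estimates
  conn <- rfm < 0.5
  diag(conn) <- FALSE
  reach <- logical(length(loci))
  reach[1L] <- TRUE
  repeat {
    newr <- reach | apply(conn[, reach, drop = FALSE], 1L, any)
    if (all(newr == reach)) break
    reach <- newr
  }
  if (!all(reach))
    stop("group is disconnected: no finite recombination-fraction chain")

  # greedy chain from the tightest pair
  ut <- which(upper.tri(rfm), arr.ind = TRUE)
  best <- ut[order(rfm[ut], loci[ut[, 1L]], loci[ut[, 2L]])[1L], ]
  chain <- loci[c(best[1L], best[2L])]
  rest <- setdiff(loci, chain)
  while (length(rest)) {
    headCost <- rfm[chain[1L], rest]
    tailCost <- rfm[chain[length(chain)], rest]
    if (min(headCost) <= min(tailCost)) {
      pick <- rest[order(headCost, rest)[1L]]
      chain <- c(pick, chain)
    } else {
      pick <- rest[order(tailCost, rest)[1L]]
      chain <- c(chain, pick)
    }
    rest <- setdiff(rest, pick)
  }

  # 2-opt segment reversals to a local SARF optimum
  L <- length(chain)
  repeat {
    improved <- FALSE
    cur <- .sarf(chain, rfm)
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        cand <- chain
        cand[i:j] <- rev(cand[i:j])
        if (.sarf(cand, rfm) < cur - 1e-12) {
          chain <- cand
          cur <- .sarf(chain, rfm)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  if (chain[L] < chain[1L]) chain <- rev(chain)
  adj <- rfm[cbind(chain[-L], chain[-1L])]
  capped <- pmin(adj, 0.4999)
  if (any(adj > 0.4999))
    warning("adjacent recombination fraction at 0.5 capped for distance")
  data.frame(locus = chain,
             position_cM = c(0, cumsum(haldaneCM(capped))))
}

#' Build an F2 linkage map
#'
#' End-to-end map construction: pairwise two-point estimation, LOD
#' grouping, per-group ordering with Haldane positions, and per-locus
#' segregation tests (distortion flagged at p < 0.05, uncorrected).
#' Groups are named `LG1`, `LG2`, ... largest first.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param lodThreshold grouping LOD threshold.
#' @param maxRf recombination-fraction ceiling for linkage edges.
#' @param distortionAlpha significance level for the distortion flag.
#' @return a [LinkageMap-class].
#' @export
buildLinkageMap <- function(geno, lodThreshold = 4, maxRf = 0.30,
                            distortionAlpha = 0.05) {
  m <- genoCodes(geno)
  pairs <- pairwiseRf(geno)
  groups <- groupLoci(pairs, lodThreshold, maxRf, loci = colnames(m))
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    ord <- if (length(g) >= 2L) orderGroup(g, pairs)
           else data.frame(locus = g, position_cM = 0)
    seg <- lapply(ord$locus, function(l) segregationChisq(m[, l]))
    data.frame(group = paste0("LG", gi), locus = ord$locus,
               position_cM = ord$position_cM,
               chi2 = vapply(seg, `[[`, numeric(1), "chi2"),
               p = vapply(seg, `[[`, numeric(1), "p"),
               df = vapply(seg, `[[`, integer(1), "df"),
               distorted = vapply(seg, `[[`, numeric(1), "p") <
                 distortionAlpha)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  new("LinkageMap", loci = d)
}

#' Per-group map summary
#'
#' One row per linkage group: map length (position of the last locus),
#' number of loci, number of distorted loci, marker density as cM per
#' marker interval (`length / (loci - 1)`, undefined and reported `NA`
#' for a single-locus group), and the distortion percentage, both
#' rounded half-up to one decimal.
#'
#' @param map a [LinkageMap-class].
#' @return summary data.frame.
#' @examples
#' # density convention: 79.9 cM over 8 loci -> 79.9/7 = 11.4 cM/interval
#' @export
mapReport <- function(map) {
  d <- mapTable(map)
  rows <- lapply(unique(d$group), function(g) {
    dd <- d[d$group == g, , drop = FALSE]
    len <- max(dd$position_cM)
    nl <- nrow(dd)
    data.frame(group = g,
               length_cM = roundHalfUp(len, 1),
               n_loci = nl,
               n_distorted = sum(dd$distorted),
               density_cM = if (nl > 1L) roundHalfUp(len / (nl - 1L), 1)
                            else NA_real_,
               distortion_pct = percentHalfUp(sum(dd$distorted), nl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
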