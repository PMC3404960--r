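# QTL detection: Haley-Knott interval mapping with permutation
# thresholds, and exhaustive genotype-combination association for
# epistatic traits.

# conditional P(QQ, Qq, qq) at a test position given the genotype sets
# observed at the nearest informative flanking markers, assuming no
# interference: each of the two gametes is an independent Markov walk
# over {first-parent allele, second-parent allele}
.condProbs <- function(rL, rR, setL, setR) {
  al <- expand.grid(L = 0:1, Q = 0:1, R = 0:1)
  wL <- if (is.null(rL)) rep(1, 8L) else ifelse(al$L == al$Q, 1 - rL, rL)
  wR <- if (is.null(rR)) rep(1, 8L) else ifelse(al$Q == al$R, 1 - rR, rR)
  w <- 0.5 * wL * wR
  p <- numeric(3L)
  for (i in 1:8) {
    for (j in 1:8) {
      gL <- al$L[i] + al$L[j]
      gR <- al$R[i] + al$R[j]
      if (!is.null(setL) && !(gL %in% setL)) next
      if (!is.null(setR) && !(gR %in% setR)) next
      gQ <- al$Q[i] + al$Q[j]
      p[gQ + 1L] <- p[gQ + 1L] + w[i] * w[j]
    }
  }
  p / sum(p)
}

# per-position additive/dominance scores for every individual:
# x_a = P(bb) - P(aa), x_d = P(heterozygote)
.hkPrepare <- function(geno, map, stepCM = 1) {
  m <- genoCodes(geno)
  d <- mapTable(map)
  if (!all(d$locus %in% colnames(m)))
    stop("map loci missing from the genotype matrix")
  n <- nrow(m)
  posRows <- list()
  XA <- list()
  XD <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, , drop = FALSE]
    mk <- dg$locus
    mp <- dg$position_cM
    codes <- m[, mk, drop = FALSE]
    miss <- codes == "-"
    pos <- sort(unique(c(seq(0, max(mp), by = stepCM), mp)))
    for (p in pos) {
      xa <- numeric(n)
      xd <- numeric(n)
      cache <- new.env(parent = emptyenv())
      for (ind in seq_len(n)) {
        lCand <- which(mp <= p & !miss[ind, ])
        rCand <- which(mp >= p & !miss[ind, ])
        iL <- if (length(lCand)) max(lCand) else NA_integer_
        iR <- if (length(rCand)) min(rCand) else NA_integer_
        key <- paste(iL, iR,
                     if (is.na(iL)) "" else codes[ind, iL],
                     if (is.na(iR)) "" else codes[ind, iR])
        pr <- cache[[key]]
        if (is.null(pr)) {
          rL <- if (is.na(iL)) NULL else haldaneR(p - mp[iL])
          rR <- if (is.na(iR)) NULL else haldaneR(mp[iR] - p)
          setL <- if (is.na(iL)) NULL else .codeSets[[codes[ind, iL]]]
          setR <- if (is.na(iR)) NULL else .codeSets[[codes[ind, iR]]]
          pr <- .condProbs(rL, rR, setL, setR)
          cache[[key]] <- pr
        }
        xa[ind] <- pr[3L] - pr[1L]
        xd[ind] <- pr[2L]
      }
      posRows[[length(posRows) + 1L]] <-
        data.frame(group = g, position_cM = p)
      XA[[length(XA) + 1L]] <- xa
      XD[[length(XD) + 1L]] <- xd
    }
  }
  list(positions = do.call(rbind, posRows),
       XA = do.call(cbind, XA), XD = do.call(cbind, XD), n = n)
}

# LOD profile for one phenotype vector given prepared scores; also
# returns coefficients when wanted
.hkProfile <- function(prep, y, coef = FALSE) {
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  P <- nrow(prep$positions)
  lod <- numeric(P)
  aa <- dd <- rep(NA_real_, P)
  for (k in seq_len(P)) {
    X <- cbind(1, prep$XA[keep, k], prep$XD[keep, k])
    fit <- lm.fit(X, y)
    rss1 <- sum(fit$residuals^2)
    lod[k] <- (n / 2) * log10(rss0 / rss1)
    if (coef) {
      aa[k] <- fit$coefficients[2L]
      dd[k] <- fit$coefficients[3L]
    }
  }
  list(lod = lod, additive = aa, dominance = dd, rss0 = rss0, n = n)
}

.alignPhenotype <- function(geno, phenotype, trait = NULL) {
  ids <- rownames(genoCodes(geno))
  if (is.data.frame(phenotype)) {
    cn <- if (is.null(trait)) setdiff(names(phenotype), "id")[1L] else trait
    y <- phenotype[[cn]][match(ids, phenotype$id)]
  } else if (!is.null(names(phenotype))) {
    y <- unname(phenotype[ids])
  } else {
    stopifnot(length(phenotype) == length(ids))
    y <- phenotype
  }
  as.numeric(y)
}

#' Haley-Knott interval mapping scan
#'
#' At every test position (a `stepCM` grid plus the marker positions of
#' each group) the conditional QTL genotype probabilities given the
#' nearest non-missing flanking markers are computed under the Haldane
#' (no-interference) model, and the phenotype is regressed on the
#' additive score `x_a = P(QQ) - P(qq)` and the dominance score
#' `x_d = P(Qq)`. `LOD = (n/2) log10(RSS0/RSS1)`; the additive and
#' dominance effects are the regression coefficients. On a fully
#' informative codominant marker the probabilities collapse to
#' indicators and the scan equals single-marker regression. The LOD
#' profile is invariant under affine transformation of the phenotype.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param map a [LinkageMap-class] sharing locus ids with `geno`.
#' @param phenotype numeric vector (aligned with or named by
#'   individuals) or a data.frame with an `id` column.
#' @param stepCM scan step in cM.
#' @param threshold optional genome-wide LOD threshold; when given,
#'   peaks are declared (see [qtlPeaks()]).
#' @param trait trait column name when `phenotype` is a data.frame.
#' @return a [QtlScanResult-class].
#' @export
hkScan <- function(geno, map, phenotype, stepCM = 1, threshold = NA_real_,
                   trait = NULL) {
  y <- .alignPhenotype(geno, phenotype, trait)
  if (stats::var(y, na.rm = TRUE) == 0)
    stop("phenotype has zero variance")
  prep <- .hkPrepare(geno, map, stepCM)
  pr <- .hkProfile(prep, y, coef = TRUE)
  profile <- cbind(prep$positions,
                   data.frame(lod = pr$lod, additive = pr$additive,
                              dominance = pr$dominance))
  res <- new("QtlScanResult", profile = profile,
             threshold = as.numeric(threshold),
             peaks = data.frame(), n = as.integer(pr$n))
  if (!is.na(threshold)) res <- qtlPeaks(res, threshold)
  res
}

#' Declare QTL peaks above a threshold
#'
#' One peak per linkage group: the position of the group's maximum LOD
#' when it exceeds the threshold, with a 1-LOD-drop support interval and
#' the fraction of phenotypic variance explained at the peak
#' (`1 - RSS1/RSS0`).
#'
#' @param result a [QtlScanResult-class].
#' @param threshold genome-wide LOD threshold.
#' @return the result with its `peaks` slot filled.
#' @export
qtlPeaks <- function(result, threshold) {
  d <- result@profile
  rows <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, , drop = FALSE]
    k <- which.max(dg$lod)
    if (dg$lod[k] < threshold) next
    drop1 <- dg$lod >= dg$lod[k] - 1
    lo <- min(dg$position_cM[drop1])
    hi <- max(dg$position_cM[drop1])
    pve <- 1 - 10^(-2 * dg$lod[k] / result@n)
    rows[[length(rows) + 1L]] <-
      data.frame(group = g, position_cM = dg$position_cM[k],
                 lod = dg$lod[k], additive = dg$additive[k],
                 dominance = dg$dominance[k],
                 support_lo_cM = lo, support_hi_cM = hi, pve = pve)
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else data.frame()
  methods::initialize(result, threshold = as.numeric(threshold),
                      peaks = peaks)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype labels, records the genome-wide maximum LOD of
#' each permutation, and returns the empirical `1 - alpha` quantile
#' (type 7). Seeded and reproducible; the scan scores are computed once
#' and reused across permutations.
#'
#' @inheritParams hkScan
#' @param nPerm number of permutations (>= 100; 1000 is conventional).
#' @param alpha genome-wide significance level.
#' @param seed integer seed.
#' @return the LOD threshold, with the vector of permutation maxima as
#'   attribute `maxLods`.
#' @export
permutationThreshold <- function(geno, map, phenotype, nPerm = 1000L,
                                 alpha = 0.05, stepCM = 1, seed = 1L,
                                 trait = NULL) {
  stopifnot(nPerm >= 100L)
  y <- .alignPhenotype(geno, phenotype, trait)
  prep <- .hkPrepare(geno, map, stepCM)
  keep <- !is.na(y)
  yk <- y[keep]
  n <- length(yk)
  # per-position orthonormal bases: RSS1 = y'y - |Q'y|^2, so each
  # permutation costs one small cross-product per position
  Qs <- lapply(seq_len(nrow(prep$positions)), function(k) {
    qrX <- qr(cbind(1, prep$XA[keep, k], prep$XD[keep, k]))
    qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  })
  set.seed(seed)
  mx <- vapply(seq_len(nPerm), function(i) {
    yp <- sample(yk)
    yty <- sum(yp^2)
    rss0 <- yty - n * mean(yp)^2
    rss1 <- vapply(Qs, function(Q) yty - sum(crossprod(Q, yp)^2),
                   numeric(1))
    max((n / 2) * log10(rss0 / rss1))
  }, numeric(1))
  th <- unname(quantile(mx, 1 - alpha, type = 7))
  attr(th, "maxLods") <- mx
  th
}

#' Exhaustive genotype-combination association search
#'
#' Enumerates all single loci and (for `maxCombo = 2`) all unordered
#' locus pairs; individuals are partitioned by their joint genotype
#' (missing at any member locus drops the individual), groups smaller
#' than `minSamples` are removed, and a one-way ANOVA F statistic is
#' computed across the remaining groups with `R^2` = between-group SS /
#' total SS. Designed for traits controlled epistatically by a small
#' number of loci, e.g. a double-recessive two-gene trait where only
#' individuals homozygous at both loci show the high phenotype class.
#' Combinations leaving fewer than two groups are skipped (recorded in
#' the `skipped` attribute).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param phenotype as in [hkScan()].
#' @param maxCombo 1 or 2, the largest combination size.
#' @param minSamples minimum individuals per joint-genotype group.
#' @param trait trait column when `phenotype` is a data.frame.
#' @return data.frame ranked by p then decreasing F, with columns
#'   `combo`, `size`, `n`, `n_groups`, `F`, `p`, `r2`.
#' @export
gmmSearch <- function(geno, phenotype, maxCombo = 2L, minSamples = 1L,
                      trait = NULL) {
  stopifnot(maxCombo %in% 1:2)
  m <- genoCodes(geno)
  y0 <- .alignPhenotype(geno, phenotype, trait)
  loci <- colnames(m)
  combos <- as.list(loci)
  if (maxCombo == 2L && length(loci) > 1L) {
    pr <- combn(loci, 2L)
    combos <- c(combos, lapply(seq_len(ncol(pr)), function(i) pr[, i]))
  }
  skipped <- character(0)
  rows <- lapply(combos, function(cb) {
    lab <- apply(m[, cb, drop = FALSE], 1L, paste, collapse = "/")
    keep <- !is.na(y0) & !grepl("-", lab, fixed = TRUE)
    y <- y0[keep]
    lab <- lab[keep]
    cnt <- table(lab)
    okg <- names(cnt)[cnt >= minSamples]
    sel <- lab %in% okg
    y <- y[sel]
    lab <- factor(lab[sel])
    if (nlevels(lab) < 2L || length(y) < 3L) {
      skipped <<- c(skipped, paste(cb, collapse = ":"))
      return(NULL)
    }
    gm <- tapply(y, lab, mean)
    ssb <- sum(tabulate(lab) * (gm - mean(y))^2)
    sst <- sum((y - mean(y))^2)
    ssw <- sst - ssb
    df1 <- nlevels(lab) - 1L
    df2 <- length(y) - nlevels(lab)
    Fv <- if (ssw <= 0 || df2 == 0L) Inf else (ssb / df1) / (ssw / df2)
    p <- if (is.infinite(Fv)) 0 else pf(Fv, df1, df2, lower.tail = FALSE)
    data.frame(combo = paste(cb, collapse = ":"),
               size = length(cb), n = length(y),
               n_groups = nlevels(lab), F = Fv, p = p,
               r2 = if (sst > 0) ssb / sst else NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  d <- do.call(rbind, rows)
  d <- d[order(d$p, -d$F, d$combo), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "skipped") <- skipped
  d
}

#' Residualize a phenotype on fixed cofactor markers
#'
#' Regresses the phenotype on the additive and dominance scores of the
#' given codominant marker loci and returns the residuals (plus the
#' phenotype mean, so the scale is preserved). Scanning the residuals
#' with [hkScan()] approximates multiple-QTL control with fixed,
#' user-chosen cofactors; it is a simple hook, not a full composite
#' interval mapping implementation, and positions linked to a cofactor
#' lose power.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param phenotype as in [hkScan()].
#' @param cofactors character vector of codominant locus ids.
#' @param trait trait column when `phenotype` is a data.frame.
#' @return data.frame with `id` and the residualized `trait`.
#' @export
residualizePhenotype <- function(geno, phenotype, cofactors,
                                 trait = NULL) {
  m <- genoCodes(geno)
  stopifnot(all(cofactors %in% colnames(m)))
  y <- .alignPhenotype(geno, phenotype, trait)
  X <- matrix(1, nrow(m), 1L)
  for (l in cofactors) {
    g <- m[, l]
    if (!all(g %in% c("a", "h", "b")))
      stop("cofactor '", l, "' must be codominant without missing data")
    X <- cbind(X, c(a = -1, h = 0, b = 1)[g], as.numeric(g == "h"))
  }
  keep <- !is.na(y)
  fit <- lm.fit(X[keep, , drop = FALSE], y[keep])
  out <- rep(NA_real_, length(y))
  out[keep] <- fit$residuals + mean(y[keep])
  data.frame(id = rownames(m), trait = out)
}

#' Per-group phenotype summary of one locus combination
#'
#' @param geno a [GenotypeMatrix-class].
#' @param phenotype as in [hkScan()].
#' @param combo character vector of locus ids (length 1 or 2).
#' @param trait trait column when `phenotype` is a data.frame.
#' @return data.frame with one row per joint-genotype group: `genotype`,
#'   `n`, `mean`.
#' @export
gmmGroups <- function(geno, phenotype, combo, trait = NULL) {
  m <- genoCodes(geno)
  y <- .alignPhenotype(geno, phenotype, trait)
  lab <- apply(m[, combo, drop = FALSE], 1L, paste, collapse = "/")
  keep <- !is.na(y) & !grepl("-", lab, fixed = TRUE)
  d <- aggregate(list(mean = y[keep]), list(genotype = lab[keep]), mean)
  d$n <- as.integer(table(lab[keep])[d$genotype])
  d[order(d$genotype), c("genotype", "n", "mean")]
}
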