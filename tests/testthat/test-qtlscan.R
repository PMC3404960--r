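scanFixture <- function(n = 200, seed = 91, sigma = 1.2247, qtl = "m004",
                        a = 1, d = 0) {
  tm <- makeTruthMap(2, 8, 10)
  g <- simulateF2(tm, n, seed = seed)
  ph <- simulatePhenotypes(g, list(type = "quantitative",
                                   qtls = data.frame(locus = qtl, a = a,
                                                     d = d),
                                   sigma = sigma), seed = seed + 1)
  map <- new("LinkageMap",
             loci = data.frame(group = tm$group, locus = tm$locus,
                               position_cM = tm$position_cM, chi2 = 0,
                               p = 1, df = 2L, distorted = FALSE))
  list(g = g, ph = ph, map = map, tm = tm)
}

test_that("on a codominant marker the scan equals single-marker regression", {
  fx <- scanFixture()
  scan <- hkScan(fx$g, fx$map, fx$ph)
  prof <- scanProfile(scan)
  y <- fx$ph$trait
  for (l in c("m002", "m004", "m012")) {
    codes <- genoCodes(fx$g)[, l]
    xa <- c(a = -1, h = 0, b = 1)[codes]
    xd <- as.numeric(codes == "h")
    fit <- lm(y ~ xa + xd)
    rss0 <- sum((y - mean(y))^2)
    lodMarker <- (length(y) / 2) * log10(rss0 / sum(residuals(fit)^2))
    row <- prof[prof$group == fx$tm$group[fx$tm$locus == l] &
                  prof$position_cM == fx$tm$position_cM[fx$tm$locus == l], ]
    expect_equal(row$lod, lodMarker, tolerance = 1e-9)
    expect_equal(row$additive, unname(coef(fit)["xa"]), tolerance = 1e-9)
    expect_equal(row$dominance, unname(coef(fit)["xd"]), tolerance = 1e-9)
  }
})

test_that("the LOD profile is invariant under affine phenotype maps", {
  fx <- scanFixture(n = 120)
  a <- hkScan(fx$g, fx$map, fx$ph)
  ph2 <- fx$ph
  ph2$trait <- 3.7 * ph2$trait - 11
  b <- hkScan(fx$g, fx$map, ph2)
  expect_equal(scanProfile(a)$lod, scanProfile(b)$lod, tolerance = 1e-8)
})

test_that("a planted QTL is detected near its true position", {
  fx <- scanFixture(seed = 191)
  th <- permutationThreshold(fx$g, fx$map, fx$ph, nPerm = 200, seed = 7)
  scan <- hkScan(fx$g, fx$map, fx$ph, threshold = th)
  pk <- scanPeaks(scan)
  expect_gte(nrow(pk), 1L)
  top <- pk[which.max(pk$lod), ]
  expect_equal(top$group, "chr1")
  expect_lt(abs(top$position_cM - 30), 10)
  expect_gt(top$pve, 0.1)
  expect_true(top$support_lo_cM <= top$position_cM &&
                top$position_cM <= top$support_hi_cM)
  # additive effect at the true QTL marker within 2 s.e. of the planted 1
  prof <- scanProfile(scan)
  atQtl <- prof[prof$group == "chr1" & prof$position_cM == 30, ]
  expect_lt(abs(atQtl$additive - 1), 2 * 1.2247 / sqrt(200 / 2))
})

test_that("permutation thresholds are seeded and quantile-monotone", {
  fx <- scanFixture(n = 100)
  t1 <- permutationThreshold(fx$g, fx$map, fx$ph, nPerm = 100, seed = 5)
  t2 <- permutationThreshold(fx$g, fx$map, fx$ph, nPerm = 100, seed = 5)
  expect_equal(as.numeric(t1), as.numeric(t2))
  mx <- attr(t1, "maxLods")
  expect_length(mx, 100L)
  expect_gte(quantile(mx, 0.99, type = 7), quantile(mx, 0.95, type = 7))
  expect_error(permutationThreshold(fx$g, fx$map, fx$ph, nPerm = 50), "100")
})

test_that("constant genotypes give a null scan and near-zero threshold", {
  codes <- matrix("a", 80, 3,
                  dimnames = list(sprintf("i%02d", 1:80), c("A", "B", "C")))
  g <- GenotypeMatrix(codes)
  map <- new("LinkageMap",
             loci = data.frame(group = "g", locus = c("A", "B", "C"),
                               position_cM = c(0, 10, 20), chi2 = 0, p = 1,
                               df = 2L, distorted = FALSE))
  set.seed(2)
  ph <- data.frame(id = rownames(codes), trait = rnorm(80))
  th <- permutationThreshold(g, map, ph, nPerm = 100, seed = 3)
  expect_lt(as.numeric(th), 1e-8)
  expect_error(hkScan(g, map, data.frame(id = rownames(codes), trait = 1)),
               "zero variance")
})

test_that("gmm R-squared equals marker-regression variance explained", {
  fx <- scanFixture(n = 150, seed = 93)
  res <- gmmSearch(fx$g, fx$ph, maxCombo = 1)
  y <- fx$ph$trait
  for (l in c("m001", "m004")) {
    codes <- genoCodes(fx$g)[, l]
    xa <- c(a = -1, h = 0, b = 1)[codes]
    xd <- as.numeric(codes == "h")
    r2lm <- summary(lm(y ~ xa + xd))$r.squared
    expect_equal(res$r2[res$combo == l], r2lm, tolerance = 1e-10)
  }
})

test_that("a fully penetrant locus is recovered with R2 = 1", {
  tm <- makeTruthMap(1, 4, 25)
  g <- simulateF2(tm, 80, seed = 94)
  ph <- simulatePhenotypes(g, list(type = "quantitative",
                                   qtls = data.frame(locus = "m002", a = 1,
                                                     d = 0.5),
                                   sigma = 0), seed = 1)
  res <- gmmSearch(g, ph, maxCombo = 1)
  expect_equal(res$combo[1], "m002")
  expect_equal(res$r2[1], 1, tolerance = 1e-12)
})

test_that("the epistatic pair outranks every single locus", {
  tm <- makeTruthMap(2, 4, 15)
  g <- simulateF2(tm, 186, seed = 95)
  ph <- simulatePhenotypes(g, list(type = "epistatic",
                                   loci = c("m002", "m006")), seed = 9)
  res <- gmmSearch(g, ph, maxCombo = 2)
  expect_equal(res$combo[1], "m002:m006")
  pairR2 <- res$r2[1]
  expect_true(all(pairR2 > res$r2[res$size == 1]))
})

test_that("missing genotypes drop individuals and groups filter by size", {
  tm <- makeTruthMap(1, 2, 30)
  g <- simulateF2(tm, 100, missingRate = 0.1, seed = 96,
                  qtlPositions = data.frame(group = "chr1",
                                            position_cM = 0, name = "Q"))
  ph <- simulatePhenotypes(g, list(type = "quantitative",
                                   qtls = data.frame(locus = "Q", a = 1,
                                                     d = 0), sigma = 1),
                           seed = 2)
  res <- gmmSearch(g, ph, maxCombo = 2, minSamples = 3)
  m <- genoCodes(g)
  ok <- rowSums(m == "-") == 0
  expect_lte(res$n[res$combo == "m001:m002"], sum(ok))
  grp <- gmmGroups(g, ph, c("m001", "m002"))
  expect_true(all(grp$n >= 1))
  expect_false(any(grepl("-", grp$genotype)))
})

test_that("cofactor residualization removes a QTL's own signal", {
  fx <- scanFixture(n = 150, seed = 98)
  resid <- residualizePhenotype(fx$g, fx$ph, "m004")
  scan <- hkScan(fx$g, fx$map, resid)
  prof <- scanProfile(scan)
  at <- prof[prof$group == "chr1" & prof$position_cM == 30, ]
  expect_lt(at$lod, 1e-8)
  expect_error(residualizePhenotype(fx$g, fx$ph, "nope"), "cofactors")
})

test_that("permuted phenotypes rarely beat the Bonferroni level", {
  tm <- makeTruthMap(2, 5, 12)
  g <- simulateF2(tm, 150, seed = 97)
  set.seed(10)
  y <- rnorm(150)
  nCombo <- 10 + choose(10, 2)
  hits <- 0L
  for (i in 1:30) {
    ph <- data.frame(id = rownames(genoCodes(g)), trait = sample(y))
    res <- gmmSearch(g, ph)
    if (min(res$p) < 0.05 / nCombo) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})
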