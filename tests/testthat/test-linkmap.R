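test_that("Haldane mapping function and inverse behave as closed forms", {
  expect_equal(haldaneCM(0), 0)
  expect_equal(haldaneCM(0.25), 34.657, tolerance = 1e-3)
  expect_equal(haldaneR(0), 0)
  for (r in c(0.01, 0.1, 0.25, 0.4, 0.49))
    expect_equal(haldaneR(haldaneCM(r)), r, tolerance = 1e-12)
  for (d in c(0, 5, 50, 200))
    expect_equal(haldaneCM(haldaneR(d)), d, tolerance = 1e-9)
  expect_warning(x <- haldaneCM(0.5), "infinite")
  expect_identical(x, Inf)
  expect_error(haldaneCM(0.6), "0, 0.5")
  expect_error(haldaneR(-1), "non-negative")
})

test_that("segregation chi-square matches hand computation", {
  sc <- segregationChisq(rep(c("a", "h", "h", "b"), 25))
  expect_equal(sc$chi2, 0)
  expect_equal(sc$p, 1)
  expect_equal(sc$df, 2L)

  # dominant 3:1 with counts 77 red (c) : 17 recessive (a)
  col <- c(rep("a", 17), rep("c", 77))
  sc <- segregationChisq(col)
  expect_equal(sc$df, 1L)
  expect_equal(sc$chi2, (17 - 23.5)^2 / 23.5 + (77 - 70.5)^2 / 70.5,
               tolerance = 1e-12)
  expect_equal(sc$chi2, 2.397, tolerance = 1e-3)
  expect_equal(sc$p, 0.1216, tolerance = 1e-3)

  # the chi-square upper tail at 0.12 on one degree of freedom is 0.73
  expect_equal(round(pchisq(0.12, 1, lower.tail = FALSE), 2), 0.73)

  expect_error(segregationChisq(rep("-", 10)), "non-missing|mixes")
  expect_error(segregationChisq(c("a", "-", "-")), "2 non-missing")
})

test_that("EM recombination fraction matches the grid-search oracle", {
  tm <- makeTruthMap(2, 5, 12)
  g <- simulateF2(tm, 150, seed = 81,
                  obsMode = c(m002 = "dominant_a", m007 = "dominant_b"))
  m <- genoCodes(g)
  pr <- utils::combn(colnames(m), 2)
  for (k in seq_len(ncol(pr))) {
    c1 <- m[, pr[1, k]]; c2 <- m[, pr[2, k]]
    em <- estimateRfF2(c1, c2)
    or <- gridRfOracle(c1, c2)
    expect_lt(abs(em$rf - or$rf), 1e-4)
    expect_lt(abs(or$llFun(em$rf) - or$ll), 1e-6)
    expect_lt(abs(em$lod - or$lod), 1e-4)
  }
})

test_that("perfect cosegregation drives the estimate to zero", {
  col <- rep(c("a", "h", "h", "b"), 20)
  em <- estimateRfF2(col, col)
  expect_lt(em$rf, 1e-5)
  or <- gridRfOracle(col, col)
  expect_equal(em$lod, or$lod, tolerance = 1e-3)
  expect_gt(em$lod, 10)
})

test_that("independent loci estimate near one half with low LOD", {
  tm <- data.frame(group = c("g1", "g2"), locus = c("A", "B"),
                   position_cM = c(0, 0))
  g <- simulateF2(tm, 200, seed = 82)
  em <- estimateRfF2(genoCodes(g)[, "A"], genoCodes(g)[, "B"])
  expect_gt(em$rf, 0.44)
  expect_lt(em$lod, 1)
})

test_that("the estimate is symmetric in locus order and line labels", {
  tm <- data.frame(group = "g", locus = c("A", "B"), position_cM = c(0, 20))
  g <- simulateF2(tm, 120, seed = 83)
  c1 <- genoCodes(g)[, "A"]; c2 <- genoCodes(g)[, "B"]
  expect_equal(estimateRfF2(c1, c2)$rf, estimateRfF2(c2, c1)$rf,
               tolerance = 1e-9)
  swap <- function(v) chartr("ab", "ba", v)
  expect_equal(estimateRfF2(c1, c2)$rf,
               estimateRfF2(swap(c1), swap(c2))$rf, tolerance = 1e-6)
})

test_that("estimateRfF2 validates input and flags repulsion dominants", {
  expect_error(estimateRfF2(rep("a", 50), rep(c("a", "h"), 25)),
               "monomorphic")
  expect_error(estimateRfF2(c("a", "h", "b", rep("-", 20)),
                            c("a", "h", "b", rep("-", 20))), ">= 10")
  c1 <- rep(c("a", "c", "c", "c"), 10)
  c2 <- rep(c("d", "d", "d", "b"), 10)
  expect_true(estimateRfF2(c1, c2)$repulsionDD)
})

test_that("LOD grouping respects thresholds and refines monotonically", {
  tm <- makeTruthMap(2, 6, 10)
  g <- simulateF2(tm, 200, seed = 84)
  pairs <- pairwiseRf(g)
  groups <- groupLoci(pairs, lodThreshold = 4)
  expect_length(groups, 2L)
  expect_setequal(groups[[1]], tm$locus[tm$group == tm$group[1]])

  # a threshold above every LOD isolates every locus
  soloT <- max(pairs$lod, na.rm = TRUE) + 1
  expect_length(groupLoci(pairs, soloT), ncol(genoCodes(g)))

  # raising the threshold never merges groups
  sweep <- sweepGroupings(pairs, thresholds = 4:10)
  for (i in seq_len(length(sweep) - 1)) {
    coarse <- sweep[[i]]
    fine <- sweep[[i + 1]]
    for (grp in fine) {
      host <- vapply(coarse, function(cg) all(grp %in% cg), logical(1))
      expect_equal(sum(host), 1L)
    }
  }
})

test_that("ordering recovers small groups exactly", {
  pairs <- data.frame(locus1 = c("A", "B", "A"), locus2 = c("B", "C", "C"),
                      rf = c(0.05, 0.05, 0.095), lod = 10, n = 100,
                      repulsionDD = FALSE, note = "")
  ord <- orderGroup(c("A", "B", "C"), pairs)
  expect_equal(ord$locus, c("A", "B", "C"))
  expect_equal(ord$position_cM[1], 0)
  expect_equal(diff(ord$position_cM), rep(haldaneCM(0.05), 2),
               tolerance = 1e-9)

  two <- orderGroup(c("X", "Y"),
                    data.frame(locus1 = "X", locus2 = "Y", rf = 0.1,
                               lod = 5, n = 50, repulsionDD = FALSE,
                               note = ""))
  expect_equal(two$position_cM, c(0, haldaneCM(0.1)), tolerance = 1e-9)
})

test_that("2-opt ordering reaches the exhaustive SARF optimum", {
  tm <- makeTruthMap(1, 8, 12)
  g <- simulateF2(tm, 150, seed = 85)
  pairs <- pairwiseRf(g)
  ord <- orderGroup(tm$locus, pairs)
  rfm <- matrix(0.5, 8, 8, dimnames = list(tm$locus, tm$locus))
  for (k in seq_len(nrow(pairs))) {
    rfm[pairs$locus1[k], pairs$locus2[k]] <- pairs$rf[k]
    rfm[pairs$locus2[k], pairs$locus1[k]] <- pairs$rf[k]
  }
  sarf <- function(o) sum(rfm[cbind(o[-length(o)], o[-1])])
  best <- min(vapply(allPerms(tm$locus), sarf, numeric(1)))
  expect_equal(sarf(ord$locus), best, tolerance = 1e-9)
  # orientation normalization: smaller terminal first
  expect_true(ord$locus[1] < ord$locus[8])
})

test_that("a group with no finite chain is rejected", {
  pairs <- data.frame(locus1 = c("A", "A", "B"), locus2 = c("B", "C", "C"),
                      rf = c(0.05, NA, NA), lod = c(10, NA, NA), n = 50,
                      repulsionDD = FALSE, note = c("", "x", "x"))
  expect_error(orderGroup(c("A", "B", "C"), pairs), "disconnected")
})

test_that("buildLinkageMap assembles groups, orders and distortion flags", {
  tm <- makeTruthMap(2, 6, 10)
  g <- simulateF2(tm, 200, seed = 86, missingRate = 0.03)
  map <- buildLinkageMap(g)
  d <- mapTable(map)
  expect_length(unique(d$group), 2L)
  expect_equal(nrow(d), 12L)
  for (grp in unique(d$group)) {
    pos <- d$position_cM[d$group == grp]
    expect_equal(pos[1], 0)
    expect_false(is.unsorted(pos))
    trueLoci <- tm$locus[tm$group == tm$group[match(d$locus[d$group == grp][1],
                                                    tm$locus)]]
    expect_gte(adjacentConcordance(trueLoci, d$locus[d$group == grp]), 0.8)
  }
})

test_that("map report reproduces the density and distortion conventions", {
  mk <- function(group, n, len, nDist) {
    data.frame(group = group, locus = paste0(group, "_", seq_len(n)),
               position_cM = seq(0, len, length.out = n),
               chi2 = 0, p = c(rep(0.01, nDist), rep(0.5, n - nDist)),
               df = 2L, distorted = c(rep(TRUE, nDist),
                                      rep(FALSE, n - nDist)))
  }
  map <- new("LinkageMap", loci = rbind(mk("LG10.1t", 8, 79.9, 3),
                                        mk("LG08.1", 38, 199.8, 6)))
  rep <- mapReport(map)
  expect_equal(rep$density_cM, c(11.4, 5.4))
  expect_equal(rep$distortion_pct, c(37.5, 15.8))
  expect_equal(rep$length_cM, c(79.9, 199.8))

  one <- new("LinkageMap",
             loci = data.frame(group = "LGx", locus = "only",
                               position_cM = 0, chi2 = 0, p = 1, df = 2L,
                               distorted = FALSE))
  expect_true(is.na(mapReport(one)$density_cM))

  two <- new("LinkageMap",
             loci = data.frame(group = "LGy", locus = c("p", "q"),
                               position_cM = c(0, 10), chi2 = 0, p = 1,
                               df = 2L, distorted = FALSE))
  expect_equal(mapReport(two)$density_cM, 10.0)
})
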