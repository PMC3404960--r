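test_that("read simulation is byte-deterministic under a seed", {
  cfg <- SimConfig(nSsrLoci = 10, nTeSites = 5, seed = 77)
  a <- simulateTwoLineReads(cfg)
  b <- simulateTwoLineReads(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(ssrTruth(a$truth), ssrTruth(b$truth))
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  writeFastaReads(a$reads, f1)
  writeFastaReads(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fracPolymorphic = 0 gives equal repeat counts in both lines", {
  cfg <- SimConfig(nSsrLoci = 30, nTeSites = 0, fracPolymorphic = 0,
                   seed = 5)
  tt <- ssrTruth(simulateTwoLineReads(cfg)$truth)
  expect_true(all(tt$count_line1 == tt$count_line2))
  expect_false(any(tt$polymorphic))
})

test_that("error-free reads contain the exact simulated tracts", {
  cfg <- SimConfig(nSsrLoci = 1, nTeSites = 0, fracPolymorphic = 1,
                   motifPool = c(AC = 1), readErrorRate = 0, seed = 9)
  sim <- simulateTwoLineReads(cfg)
  tt <- ssrTruth(sim$truth)
  expect_true(tt$count_line1 != tt$count_line2)
  for (li in 1:2) {
    cnt <- c(tt$count_line1, tt$count_line2)[li]
    rd <- sim$reads[grepl(paste0("^line", li, "\\|"), names(sim$reads))]
    expect_true(all(grepl(strrep("AC", cnt), rd, fixed = TRUE)))
    tr <- findTracts(rd)
    expect_true(all(tr$repeat_count == cnt))
  }
})

test_that("TE sites emit junction reads only from carrier lines", {
  cfg <- SimConfig(nSsrLoci = 0, nTeSites = 30, fracTeLineSpecific = 0.5,
                   readErrorRate = 0, seed = 13)
  sim <- simulateTwoLineReads(cfg)
  tt <- teTruth(sim$truth)
  lineOf <- sub("\\|.*", "", names(sim$reads))
  locOf <- sub("^[^|]*\\|([^|]*)\\|.*", "\\1", names(sim$reads))
  for (i in seq_len(nrow(tt))) {
    lines <- unique(lineOf[locOf == tt$locus[i]])
    expect_setequal(lines, c("line1", "line2")[c(tt$in_line1[i],
                                                 tt$in_line2[i])])
  }
  # carrier reads contain the consensus verbatim (no errors simulated)
  expect_true(all(grepl(sim$truth@teConsensus, sim$reads[locOf == tt$locus[1]],
                        fixed = TRUE)))
})

test_that("simulator rejects bad configurations", {
  expect_error(SimConfig(fracPolymorphic = 1.2), "fractions")
  expect_error(SimConfig(motifPool = c(ACN = 1)), "ACGT")
  expect_error(SimConfig(flankLen = 40), "flankLen")
  expect_error(simulateTwoLineReads(SimConfig(motifPool = c(ATAT = 1),
                                              nSsrLoci = 1, nTeSites = 0)),
               "primitive")
  expect_warning(simulateTwoLineReads(
    SimConfig(nSsrLoci = 1, nTeSites = 0, repeatCountRange = c(3L, 5L),
              seed = 1)), "detection")
})

test_that("zero-distance loci never recombine", {
  tm <- data.frame(group = "g", locus = c("A", "B"), position_cM = c(0, 0))
  g <- simulateF2(tm, 50, seed = 3)
  m <- genoCodes(g)
  expect_true(all(m[, "A"] == m[, "B"]))
})

test_that("loci on different groups are unlinked", {
  tm <- data.frame(group = c("g1", "g2"), locus = c("A", "B"),
                   position_cM = c(0, 0))
  g <- simulateF2(tm, 400, seed = 21)
  r <- estimateRfF2(genoCodes(g)[, "A"], genoCodes(g)[, "B"])
  expect_gt(r$rf, 0.44)
  expect_lt(r$lod, 1)
})

test_that("a 34.657 cM interval recombines at fraction 0.25", {
  # inverse Haldane of 34.657 cM is exactly 0.25
  expect_equal(haldaneR(34.657), 0.25, tolerance = 1e-4)
  tm <- data.frame(group = "g", locus = c("A", "B"),
                   position_cM = c(0, 34.657))
  g <- simulateF2(tm, 500, seed = 8)
  r <- estimateRfF2(genoCodes(g)[, "A"], genoCodes(g)[, "B"])
  se <- sqrt(0.25 * 0.75 / 1000)   # 1000 gametes
  expect_lt(abs(r$rf - 0.25), 3 * se)
})

test_that("undistorted loci segregate 1:2:1", {
  tm <- makeTruthMap(1, 4, 20)
  g <- simulateF2(tm, 500, seed = 14)
  for (l in colnames(genoCodes(g))) {
    sc <- segregationChisq(genoCodes(g)[, l])
    expect_gt(sc$p, 0.01)
  }
})

test_that("adjacent intervals reproduce their inverse-Haldane fractions", {
  tm <- makeTruthMap(1, 6, 15)
  g <- simulateF2(tm, 500, seed = 17)
  m <- genoCodes(g)
  rTrue <- haldaneR(15)
  se <- sqrt(rTrue * (1 - rTrue) / 1000)
  for (j in 1:5) {
    r <- estimateRfF2(m[, j], m[, j + 1])
    expect_lt(abs(r$rf - rTrue), 3 * se)
  }
})

test_that("viability distortion produces distorted segregation", {
  tm <- data.frame(group = "g", locus = c("A", "B"), position_cM = c(0, 120))
  g <- simulateF2(tm, 400, distortion = list(A = c(0.1, 1, 1)), seed = 19)
  scA <- segregationChisq(genoCodes(g)[, "A"])
  scB <- segregationChisq(genoCodes(g)[, "B"])
  expect_lt(scA$p, 0.05)
  expect_gt(scB$p, 0.01)
  # the 'a' class is depleted, not enriched
  expect_lt(scA$counts[["a"]], 0.25 * sum(scA$counts))
})

test_that("dominant observation and missingness are applied as coded", {
  tm <- makeTruthMap(1, 3, 20)
  g <- simulateF2(tm, 300, missingRate = 0.1, seed = 23,
                  obsMode = c(m001 = "dominant_a", m002 = "dominant_b"))
  m <- genoCodes(g)
  expect_true(all(m[, "m001"] %in% c("a", "c", "-")))
  expect_true(all(m[, "m002"] %in% c("b", "d", "-")))
  expect_true(all(m[, "m003"] %in% c("a", "h", "b", "-")))
  expect_gt(mean(m == "-"), 0.05)
  expect_lt(mean(m == "-"), 0.15)
  expect_error(simulateF2(tm, 1), "at least 2")
})

test_that("hidden QTL positions are co-simulated and linked to flankers", {
  tm <- makeTruthMap(1, 4, 10)
  g <- simulateF2(tm, 300, seed = 29,
                  qtlPositions = data.frame(group = "chr1",
                                            position_cM = 15,
                                            name = "Q"))
  q <- attr(g, "qtlGeno")
  expect_equal(colnames(q), "Q")
  r <- estimateRfF2(genoCodes(g)[, "m002"], q[, "Q"])
  expect_lt(r$rf, haldaneR(5) + 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("noise-free additive phenotype equals allele dosage", {
  tm <- makeTruthMap(1, 3, 20)
  g <- simulateF2(tm, 60, seed = 31)
  ph <- simulatePhenotypes(g, list(type = "quantitative",
                                   qtls = data.frame(locus = "m002",
                                                     a = 1, d = 0),
                                   sigma = 0), seed = 1)
  dos <- c(a = -1, h = 0, b = 1)[genoCodes(g)[, "m002"]]
  expect_equal(ph$trait, unname(dos))
})

test_that("epistatic trait is high only for double homozygotes", {
  tm <- data.frame(group = c("g1", "g2"), locus = c("A", "B"),
                   position_cM = c(0, 0))
  g <- simulateF2(tm, 400, seed = 37)
  ph <- simulatePhenotypes(g, list(type = "epistatic",
                                   loci = c("A", "B")), seed = 2)
  m <- genoCodes(g)
  dbl <- m[, "A"] == "b" & m[, "B"] == "b"
  expect_gt(min(ph$trait[dbl]), max(ph$trait[!dbl]))
  # heterozygous at one locus -> low class
  het1 <- m[, "A"] == "h" & m[, "B"] == "b"
  expect_true(all(ph$trait[het1] < 15))
  expect_error(simulatePhenotypes(g, list(type = "epistatic",
                                          loci = c("A", "nope"))),
               "unknown locus")
})

test_that("double-homozygote fraction fits the Mendelian 1/16", {
  tm <- data.frame(group = c("g1", "g2"), locus = c("A", "B"),
                   position_cM = c(0, 0))
  g <- simulateF2(tm, 1600, seed = 41)
  m <- genoCodes(g)
  nDbl <- sum(m[, "A"] == "b" & m[, "B"] == "b")
  expect_gt(stats::binom.test(nDbl, 1600, 1 / 16)$p.value, 0.01)
})

test_that("F2 and phenotype generators are seed-deterministic", {
  tm <- makeTruthMap(1, 4, 10)
  expect_identical(genoCodes(simulateF2(tm, 40, seed = 6)),
                   genoCodes(simulateF2(tm, 40, seed = 6)))
  g <- simulateF2(tm, 40, seed = 6)
  mdl <- list(type = "quantitative",
              qtls = data.frame(locus = "m001", a = 1, d = 0.5), sigma = 1)
  expect_identical(simulatePhenotypes(g, mdl, seed = 3),
                   simulatePhenotypes(g, mdl, seed = 3))
})
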