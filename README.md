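# ssrmite

Marker development for crop genetics the *in silico* way: given
enriched-library reads from **two inbred lines**, find the loci whose
genotype can be scored by a cheap PCR assay — microsatellites (SSRs)
whose repeat count differs between the lines, and miniature
inverted-repeat transposable element (MITE) insertions present in only
one line — and then use such markers downstream to build F2 linkage
maps and to detect quantitative trait loci (QTLs) and epistatic locus
pairs.

The package is aimed at plant-genetics groups that genotype mapping
populations with SSR/transposon markers and want a tested, scriptable
replacement for the classic tool chain (repeat finder + assembler +
primer picker + proprietary mapping/QTL software), plus a simulator
that generates every input with known ground truth.

## What it computes

**Marker discovery.** Perfect repeat tracts with primitive unit of 2–4
bases are detected and canonicalized so that e.g. TC/GA/AG all tally as
the (CT)n class. Reads from both lines are clustered into loci by
flanking-sequence identity: the feature interval is excised, candidate
pairs are pre-filtered on shared canonical k-mers, and pairs are
connected when a global alignment of their flanks reaches 95 % identity
over ≥ 40 columns (gaps count as columns); clusters are single-linkage
components. A cluster is a *polymorphic* SSR candidate iff the per-line
majority-vote repeat counts differ, and a *cultivar-specific* MITE
insertion iff its junction reads come from exactly one line. Primer
pairs are picked on the flanks (window 18–27 nt, Tm 57–63 °C by the
unified nearest-neighbor model at 50 mM Na⁺ / 250 nM primer, GC
0.30–0.70, product 80–400 bp), falling back to the transposon interior
when a junction flank is too short.

**F2 genetics.** Per-locus segregation χ² (1:2:1 codominant, 3:1
dominant); two-point recombination fractions by an EM algorithm that
maximizes the multinomial likelihood over all codominant/dominant code
combinations, with LOD = log₁₀ L(r̂) − log₁₀ L(0.5); single-linkage
grouping at LOD ≥ 4 (sweep 4–10) and r̂ ≤ 0.30; ordering by greedy
chain extension plus 2-opt minimization of the sum of adjacent
recombination fractions; positions by Haldane's mapping function
d = −50·ln(1 − 2r) cM. QTL scans use Haley–Knott regression of the
phenotype on conditional additive/dominance scores from the nearest
informative flanking markers, with genome-wide thresholds from
permutation tests, and an exhaustive genotype-combination search
(locus pairs, one-way ANOVA F / R²) for double-recessive epistatic
traits such as the seed oleic/linoleic (O/L) ratio.

**Simulation.** `simulateTwoLineReads()`, `simulateF2()` and
`simulatePhenotypes()` generate reads, genotype matrices and phenotypes
with full truth records (`SimTruth`), under Haldane (no-interference)
meiosis, optional viability-selection segregation distortion, dominant
observation modes and missing data. Every generator is byte-reproducible
from its seed.

## Worked example

```r
library(ssrmite)

cfg <- SimConfig(nSsrLoci = 40, nTeSites = 15, fracPolymorphic = 0.3,
                 seed = 7)
sim <- simulateTwoLineReads(cfg)                     # 408 reads
ann <- ssrAnnotations(sim$reads)
te  <- teAnnotations(sim$reads[setdiff(names(sim$reads), ann$read)],
                     sim$truth@teConsensus)
clusters <- clusterReads(sim$reads, rbind(ann, te))  # 55 clusters
cand <- screenClusters(clusters, cfg@lineNames)
screenReport(cand)
#>   marker_type n_total n_polymorphic pct_polymorphic n_monomorphic ...
#> 1         SSR      40            12            30.0            27
#> 2          TE      15             8            53.3             7
```

Of 40 simulated SSR loci, 12 (30.0 %) are called polymorphic — the
fraction the simulation planted — and 8 of 15 MITE sites are
line-specific. A primer pair for the first polymorphic SSR candidate:

```r
i <- which(cand$class == "polymorphic" & cand$marker_type == "SSR")[1]
designPrimers(cand$template[i], cand$feature_start[i],
              cand$feature_end[i])[1, ]
#>   left_seq             right_seq            left_tm right_tm product_len
#> 1 CCCACCTCCATTCGAGCTGC GCACGCTAGCATGTCCTCGT    59.6     59.4         226
```

The product lengths on the two lines differ by (Δ repeat count) × motif
length, which is what makes the marker scorable on a fragment analyzer.
Downstream, a simulated F2 of 200 individuals over two chromosomes:

```r
tm <- data.frame(group = rep(c("chr1", "chr2"), each = 8),
                 locus = sprintf("m%02d", 1:16),
                 position_cM = rep(seq(0, 70, 10), 2))
geno <- simulateF2(tm, 200, seed = 11)
map <- buildLinkageMap(geno)
mapReport(map)
#>   group length_cM n_loci n_distorted density_cM distortion_pct
#> 1   LG1      69.5      8           2        9.9             25
#> 2   LG2      67.1      8           0        9.6              0

ph <- simulatePhenotypes(geno, list(type = "quantitative",
        qtls = data.frame(locus = "m04", a = 1, d = 0), sigma = 1.22),
        seed = 5)
th <- permutationThreshold(geno, map, ph, nPerm = 200, seed = 2)  # 2.45
scan <- hkScan(geno, map, ph, threshold = th)
scanPeaks(scan)
#>   group position_cM  lod additive dominance support_lo support_hi  pve
#> 1   LG1          35 13.9     1.04     -0.15         31         42 0.27
```

The planted QTL (30 cM, additive effect 1, ~25 % variance explained) is
recovered at 35 cM with LOD 13.9 against a permutation threshold of
2.45; the 1-LOD support interval spans 31–42 cM.

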