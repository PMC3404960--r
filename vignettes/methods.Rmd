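---
title: "Methods: in silico marker discovery and F2 genetics in ssrmite"
author: "ssrmite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico marker discovery and F2 genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models and algorithmic choices behind the
package, in the order data flow through it: repeat detection, read
clustering, polymorphism classification, primer design, linkage
mapping, QTL and epistasis analysis, and the simulator that backs the
test suite. It also states which features of real data the simulator
does and does not emulate, so it is clear what a green test suite does
and does not establish.

## SSR detection and motif canonicalization

`findTracts()` reports **perfect** repeat tracts with a primitive unit
of 2–4 bases, at least 6 copies for dinucleotides and 5 for tri- and
tetranucleotides by default. Any mismatch splits a tract; there is no
imperfection tolerance at this layer (error tolerance is handled one
layer up, see below). Mononucleotide runs and units of 5–6 bases are
not scanned: they are not scored in the marker systems the package
targets, and homopolymers are a notorious source of sequencing
artifacts. When maximal tracts overlap, the longer wins, with ties to
the smaller start; a run reported under several phases is merged to
one tract. The scanner is validated against a brute-force
start-by-start oracle on a thousand random sequences.

A repeat class must not depend on the strand or phase a read happened
to sample. `canonicalMotif()` therefore maps every rotation and the
reverse complement of a motif to one representative. A plain
lexicographic minimum over both strands' rotations would name the
CT/TC/GA/AG family "AG"; the package instead takes the smallest
rotation on the **pyrimidine-richer strand** (ties consider both
strands), which yields the class names in conventional use for
dinucleotide microsatellites, (AC)n and (CT)n, while remaining
idempotent and strand/rotation invariant.

## Read clustering by flank identity

The unit of polymorphism classification is a cluster of reads from
both lines that represent one genomic locus. Assembly of whole reads
would be defeated by the very signal we are after — a 10-copy versus
12-copy tract shifts the alignment — so the feature interval is
**excised** and reads are compared over their concatenated flanks:
candidate pairs must share at least 3 canonical 15-mers, then a global
alignment must reach 95 % identity over at least 40 columns, with gaps
counted as columns. Clusters are single-linkage connected components,
mirroring transitive contig growth; ids are assigned from the
lexicographically smallest member read so output is independent of
input order. Equal-anchored flank pairs take a gap-free fast path
whose identity lower-bounds the alignment, so the dynamic program runs
only for the rare borderline pairs.

A substitution error *inside* a tract splits it into a detected run
plus a residual run; naive excision then leaves repeat residue in one
read's flank and costs ~5 % identity, enough to break the 95 %
criterion. `ssrAnnotations()` therefore widens the excised interval
over bases that continue the tract's periodicity, tolerating up to two
substitutions per side (one substitution breaks the lag-k comparison
at two offsets, hence a mismatch budget of four), and measures the
per-read repeat count by tiling motif-length windows outward from the
detected anchor, counting a one-mismatch window only when the next
window outward is perfect. The count of an error-carrying read thus
stays at the true value instead of collapsing to the longer fragment,
which is what keeps the within-line majority vote well behaved at
realistic error rates.

## Polymorphism classification

For SSR clusters the per-line consensus is a majority vote over member
repeat counts; the cluster is *polymorphic* iff the consensuses differ,
*monomorphic* iff equal, *single_line* when only one line contributed
reads, and *conflicted* when members disagree on the motif class or a
vote ties. Conflicted clusters are excluded from candidate lists
rather than guessed at: within-line disagreement is exactly the
situation that produces false positives in downstream wet-lab
screening. The default of one read per line reflects how
singlet-versus-contig comparisons are treated in enrichment-library
screens; it is configurable.

Transposon junctions are called by local alignment of each read to the
element consensus (≥ 30 aligned columns at ≥ 80 % identity, both
strands; thresholds loose enough to tolerate terminal-inverted-repeat
divergence between family members). A junction cluster is a
cultivar-specific — and hence marker-grade — insertion iff its members
come from exactly one line. Both feature types may coexist in one
cluster and then yield two distinct candidates.

## Primer design and melting temperature

`designPrimers()` enumerates 18–27-nt windows on both flanks (the
right primer as reverse complement), filters on Tm 57–63 °C, GC
0.30–0.70, homopolymers ≤ 4, and 3′-end self/cross exact
complementarity ≤ 4 bases, pairs windows under a product range of
80–400 bp, and ranks by a penalty of weighted deviations from length
20 / Tm 60 / GC 0.5 plus the pair ΔTm, with deterministic tie-breaks
(leftmost, then shortest product). The numeric constraints mirror
common defaults for SSR genotyping assays and are all configurable.
The dimer check is exact-complement suffix matching, not a
thermodynamic duplex model — simpler and directly testable. When a
transposon candidate lacks one flank, the deficient primer is drawn
from the element interior, the standard fallback for junction assays.

Melting temperatures use the unified nearest-neighbor parameter set
with terminal initiation terms, the entropic salt correction
0.368·(N−1)·ln[Na⁺], and the C/4 concentration term, at fixed 50 mM
monovalent cation and 250 nM primer. The conditions are part of the
public contract so that reported Tm values are reproducible; the test
suite pins the implementation to values computed independently with
Biopython's implementation of the same parameter table to 0.1 °C.

## F2 linkage mapping

Genotypes use the standard F2 coding: `a`/`h`/`b` codominant, `c`
(= not `a`) and `d` (= not `b`) dominant, `-` missing; a locus must be
coded consistently. Segregation is tested against 1:2:1 (df 2) or 3:1
(df 1) without continuity correction; distortion is flagged at
p < 0.05 without multiple-testing correction, matching how distortion
ratios are conventionally reported per group.

Two-point recombination fractions are maximum-likelihood estimates
under the standard F2 two-locus multinomial. Rather than special-casing
the double-heterozygote mixture and each dominant collapsing, the EM
treats the **ordered gamete pair** (16 states) as the latent variable:
the E step distributes each observed class over its compatible states
and imputes the expected number of recombinant gametes, the M step
divides by 2n. Iteration stops at |Δr| < 1e-6 with r in [0, 0.5];
LOD = log₁₀ L(r̂) − log₁₀ L(0.5). Dominant×dominant pairs in repulsion
are flagged as nearly uninformative. Every estimate in the test suite
is checked against a grid-search oracle built from the closed-form
class probabilities; the oracle's 2001-point grid is refined once
inside the winning interval because a single 2001-point grid has a
spacing of 2.5e-4, coarser than the 1e-4 agreement the suite demands.

Grouping is single-linkage over edges with LOD ≥ threshold (default
4.0, the permissive end of the conventional 4–10 sweep, for which a
sweep utility exists) and r̂ ≤ 0.30. Ordering replaces proprietary
regression mapping with a transparent two-stage heuristic: greedy
chain extension from the tightest pair, then 2-opt segment reversals
minimizing the sum of adjacent recombination fractions (SARF) to a
local optimum — exhaustive enumeration on groups of ≤ 8 loci confirms
the optimum is reached at test sizes. Positions are chained Haldane
distances of adjacent r̂ (not multipoint regression), a documented
divergence that slightly inflates map length at finite n because
adjacent estimates are noisy; group-length recovery is therefore
checked within 15 % rather than exactly. Map density is reported as
cM per marker *interval*, length/(loci − 1) — the convention verified
to reproduce published per-group density cells (79.9 cM over 8 loci →
11.4; 199.8 over 38 → 5.4), where length/loci does not. Percentages
and densities round half-up to one decimal, as in the bookkeeping
tables they emulate.

## QTL scanning and epistasis

`hkScan()` performs Haley–Knott regression: at each step position the
conditional QTL genotype distribution given the nearest non-missing
flanking markers is computed under Haldane independence by
enumerating the 64 ordered gamete-pair allele configurations (this
handles dominant codes and single-flank edges uniformly), and the
phenotype is regressed on x_a = P(QQ) − P(qq) and x_d = P(Qq);
LOD = (n/2)·log₁₀(RSS₀/RSS₁). Only the nearest informative flanking
markers are used — no full hidden-Markov multipoint smoothing — which
is adequate at the marker densities simulated here (10 cM) but will
lose a little information with sparse or heavily missing maps.
Permutation thresholds shuffle the phenotype and take the type-7
empirical quantile of the genome-wide maximum LOD; the per-position
regression bases are orthonormalized once, so each permutation costs
one small cross-product per position. Peaks get a 1-LOD-drop support
interval (a conventional rule; the drop depth is a parameter of the
reporting, not of detection) and PVE = 1 − RSS₁/RSS₀.

The genotype-combination search enumerates all single loci and
unordered pairs, partitions individuals by joint genotype, drops
groups below a minimum size, and ranks combinations by one-way ANOVA
p then F, with R² = between-group SS / total SS. On a single
codominant locus this R² equals marker-regression PVE exactly (both
models span the same column space), which the suite asserts
numerically. The intended use case is a double-recessive two-gene
trait: only double homozygotes show the high class, so neither locus
alone explains the variance but the pair does.

Composite interval mapping with automatic cofactor selection is out of
scope; the simple interval mapping here plus the combination search
covers detection and the epistatic case, and a fixed-cofactor
residualization can be layered on by regressing the phenotype on
cofactor markers beforehand.

## The simulator and what it does (not) emulate

`simulateTwoLineReads()` draws locus flanks i.i.d. uniform over ACGT
and rejects any pair of loci sharing a canonical 20-mer, so cluster
precision tests measure the algorithm rather than accidental homology.
Polymorphic SSR loci differ by 1–2 repeat copies between lines;
transposon sites are line-specific with the configured probability and
emit junction reads only from carrier lines, as in an
enrichment-library protocol. Errors are i.i.d. substitutions (0.5 %
per base by default, a stand-in for trimmed capillary-read quality; no
published per-base error model exists for the data the package
emulates); an indel rate exists but defaults to 0 so repeat counts in
reads stay exact. `simulateF2()` builds each individual from two
independent gamete walks with inverse-Haldane recombination per
interval — no crossover interference, matching the mapping function
used downstream — applies distortion as viability rejection sampling
(the simplest mechanism that reproduces a distorted χ²), then dominant
observation and missingness. The epistatic phenotype's class
parameters (low 1.0 ± 1.5, high 30 ± 4) follow the shape of
segregating seed O/L measurements, where the low class sits near the
normal parent (~1), the high class reaches the mutant parent's range
(up to ~35), and within-class spread includes background genetic
variation, giving a pair R² near 0.9.

Deliberately **not** emulated: homoeologous cross-amplification
between subgenomes of a polyploid (a false-positive source for both
marker types in real data), chimeric or vector-contaminated reads,
quality scores, coverage biases, and interference in meiosis. Passing
recovery tests therefore demonstrates algorithmic correctness under
the stated error model, not robustness to polyploid artifacts — on
real tetraploid data the polymorphic-call precision will be lower for
reasons the simulator cannot show.

## Numerical and testing choices

Seeds determine every stochastic output byte-for-byte. EM tolerance is
1e-6 on r; Haldane composition round-trips to 1e-12; r = 0.5 maps to
an explicit infinite distance (a warning, with a 0.4999 cap only
inside `orderGroup()`, where a pathological adjacent pair should not
poison whole-map positions). Degenerate inputs error early with
located messages: mixed genotype codings, monomorphic loci,
zero-variance phenotypes, all-missing columns, disconnected ordering
groups. Test problem sizes were chosen to keep the default suite at a
few minutes on one CPU: 1000 random sequences for the scanner oracle,
200 loci for discovery recovery, 2 × 15 loci × 200 individuals for
linkage/QTL recovery, 200 permutations and 20 null replicates for the
threshold checks (1000 permutations remains the analysis default), and
n = 186 for the epistasis search. The null-specificity check sits at
its own expectation (a 5 % genome-wide error rate), so its seeded
realizations hover at the bound by construction; the suite fixes seeds
and the acceptance script reports the realized fraction.
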