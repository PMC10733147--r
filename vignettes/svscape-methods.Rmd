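---
title: "Methods: repeat-aware characterization of structural-variant landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware characterization of structural-variant landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svscape)
```

# Scope and model

svscape characterizes a joint-genotyped catalogue of insertion/deletion
variants (large indels, 20–49 bp; structural variants, ≥ 50 bp) across a
multi-community cohort. Its core is a repeat-context classifier built on
*extended local alleles*, surrounded by cohort-level analyses: sharedness
and geography labels, novelty grading against external annotation sets,
discovery curves, telomere-distance density, gene-constraint densities
across LOEUF deciles, STR expansion discovery and diploid genotyping, and
population structure (Bray–Curtis PCOA, Weir–Cockerham FST). Because the
cohorts this kind of study rests on are access-restricted, the package
ships a first-class synthetic cohort generator that emulates the
statistical structure the analyses assume and provides ground truth for
every stage.

# The repeat classifier

## Extended local alleles

For each variant we build a sequence five times the variant size: reference
flanks of twice the variant size on each side, with the variant in the
middle (the central 20%). Insertions contribute their consensus inserted
sequence (the ALT allele); deletions contribute the deleted reference
sequence in context (the REF allele). At contig edges the flanks are
clipped and the variant-region indices are tracked explicitly rather than
recomputed as "central 20%", so clipped alleles remain correct.

## Built-in detectors

Two simplified detectors scan each allele; adapters
(`parse_trf_dat()`, `parse_repeatmasker_out()`) let users substitute real
Tandem Repeats Finder / RepeatMasker output when available.

**Tandem arrays.** For every period $p$ from 1 to 500, position $i$
matches when $s_i = s_{i-p}$. Maximal scoring segments (match $+2$,
mismatch $-7$; Kadane-style segmentation: a segment is emitted at its best
prefix when the running score falls to zero) are kept when the score
reaches 50 and the purity (matching fraction) reaches 0.8 — the classic
recommended parameterization (2 7 7 80 10 50 500) of tandem-repeat
scanning. A $p$-periodic array is trivially $np$-periodic, so calls that
are ≥ 80% covered by a smaller-period call are suppressed; each region is
therefore reported at its smallest qualifying period, with the motif
taken as the modal $p$-mer among its units. One consequence worth knowing:
with score threshold 50 and match weight 2, an array needs at least 26
matching positions, so homopolymers under ~27 bp are genuinely below the
detection floor (the synthetic generator plants 30–45 bp homopolymers for
this reason).

**Interspersed elements.** Exact 15-mer seeds shared with a library
consensus (both orientations) are chained along a common alignment
diagonal across gaps of at most 50 bp; a chain is reported when its
ungapped identity is at least 0.8, with the consensus fraction equal to
covered consensus bp over consensus length. The matcher tolerates
substitutions but not indels — a deliberate trade: on the generator's
planted (by default mismatch-free) repeats it is an exact oracle, and
real-data users are expected to plug in RepeatMasker output through the
adapter instead.

## Decision rule

Periods map to classes as 1 = HOMO, 2–12 = STR, > 12 = TR. The variant
region must be covered at ≥ 75% (union coverage) by annotations of a
single type. Tandem classes are evaluated before interspersed families —
the scans are described sequentially and no precedence is stated for the
rare case where both reach 75%, so we follow the narrative order; ties
between tandem classes resolve toward the larger period class, because a
pure $p$-array also qualifies at every multiple of $p$. A mobile-element
variant is a *complete* transposition when it contains ≥ 75% of at least
one whole canonical element, otherwise a *fragment*. Variants reaching no
threshold are non-repetitive (NONREP). Homopolymer calls are flagged and
excluded from downstream analyses by default (they are enriched for
long-read sequencing artefacts); a toggle retains them.

# The synthetic cohort

`make_reference()` plants pure STR arrays (default periods 2–6, 15–40
copies), TR arrays (unit lengths 13–48, 5–15 copies), full mobile-element
consensus copies, and gene models across ten LOEUF deciles on a
random-base backbone (default two chromosomes of 600 kb). The element
library tracks the canonical human length scales: a 280 bp SINE-like
element, a 6 kb LINE-like element and a 2 kb retroposon-like element,
plus LTR-like (500 bp) and DNA-transposon-like (800 bp) elements. Genes
avoid each other but not the repeat arrays — intronic and flanking repeats
are a feature of real genomes, and STR-in-gene sites are needed by the STR
analyses.

`simulate_cohort()` defaults to four focal communities of 10 diploid
individuals plus a 10-individual outgroup. Each variant gets an ancestral
frequency $p \sim U(0.05, 0.95)$; community frequencies follow the
Balding–Nichols model, $\mathrm{Beta}(p(1-\theta)/\theta,
(1-p)(1-\theta)/\theta)$ with default $\theta = 0.10$ (a realistic
between-population divergence for strongly structured human groups; its
expectation equals FST, which makes estimator recovery directly testable).
Genotypes are binomial draws per diploid. Configurable fractions of
variants are constrained to geography classes (private, focal-only,
outgroup-only, community-private); every emitted variant is conditioned to
have at least one carrier, which perturbs very rare loci slightly — the
law-of-large-numbers test budgets for this. Tandem variants are whole-unit
expansions/contractions of planted arrays; element variants insert the
full consensus or a contiguous slice (15–55%); non-repetitive variants are
random sequence. With telomere enrichment on (the default), 70% of TR
variants are drawn from arrays inside the chromosome-end regions (10% of
chromosome length, the scaled analogue of the ~5 Mb telomeric window on a
full-size chromosome), reproducing the qualitative density pattern the
telomere-distance analysis looks for.

What the generator does **not** emulate: sequencing error (beyond an
optional ≤ 5% substitution rate on planted repeats), indel-containing
repeat copies, nested repeats, linkage/recombination structure, sex
chromosomes and somatic events. Passing tests therefore demonstrate
algorithmic correctness on clean, truth-known data — not robustness to the
full messiness of real long-read callsets.

# Cohort-level definitions

* **Sharedness**: private (1 individual), polymorphic (> 1 and < 50% of
  individuals), major (≥ 50% but not all), shared (all). Private takes
  precedence when one individual is half a tiny cohort.
* **Geography**: focal-only / focal-absent / global by whether carriers
  are confined to the focal set, the outgroup, or neither.
* **Community spread** (focal-only variants): private; community-specific
  (> 1 individual, one community); widespread (> 1 community); shared
  (present in every focal community). We read "in all communities" as
  presence in each community, with more than one carrier overall.
* **Reciprocal overlap**: deletions use mutual interval overlap
  (equivalently shared bp over the larger length). Point-like insertions
  have no footprint, so their overlap is defined as the size ratio
  `min(svlen)/max(svlen)` gated on breakpoints within 200 bp — the same
  window the benchmarking criteria use. Novelty bands: high (> 0.80),
  moderate (0.50–0.80, closed at both ends), low ((0, 0.50)), none (0);
  high + moderate count as annotated. A per-variant mapping table stands
  in for coordinate lift-over; absent entries are UNMAPPED.
* **Merging and benchmarking**: matches require same type, reciprocal
  overlap ≥ 0.5 and breakpoints within 200 bp. Merging is single-linkage
  over cross-sample matches with the highest-QUAL member as
  representative (a deliberately simplified surrogate for graph-based
  production mergers). Benchmarking matches calls to truth one-to-one,
  greedily by descending overlap; precision = TP/(TP+FP), recall =
  TP/(TP+FN).
* **Discovery curves**: cumulative distinct-variant counts as individuals
  are added, averaged over 10 random addition orders (the single order
  used in practice is not identifiable, so we report the permutation
  mean), fitted as $a + b\ln n$ by least squares.
* **Telomere density**: distance to the nearest chromosome end, binned at
  500 kb (configurable; toy genomes need smaller bins), counts averaged
  over the chromosomes that possess each bin, optionally smoothed with a
  local-linear tricube fit (span 0.75) on log(count + 1).
* **CNV regions**: calls with $P > 10^{-4}$ excluded; single-linkage
  clusters on strict > 50% reciprocal overlap; regions span the union of
  members and report only fully contained genes. The written carrier
  classes leave count 2 and count = all unassigned as literally phrased;
  we read "polymorphic" as more-than-one and add a shared class for
  all-carrier regions.

# Constraint and STR analyses

Variant density per LOEUF decile is the count of variants touching CDS
(or non-CDS: padded gene span minus CDS, pad 2 kb) divided by the merged
region size of that decile. A variant hitting genes in several deciles
counts once, in the most constrained decile. Fold differences are plain
density ratios; the normalized view divides each type's densities by its
decile-10 value.

Canonical STR motifs collapse all rotations of a motif and of its reverse
complement to the lexicographic minimum. Significant expansions require,
conjunctively: period ≥ 3 bp, ≥ 10 repeat units gained, gain ≥ 50% of the
reference element, and a reference element < 1 kb. Diploid genotyping
applies each haplotype's phased variants to the local reference and
extracts a ±50 bp window around the site; the longer allele is allele A,
and the tandem detector supplies period and motif. Cross-community
variability uses a one-way ANOVA on allele lengths with both alleles of
an individual entering as observations — pseudo-replication, reproduced
deliberately for fidelity to the procedure it mirrors — and per-community
standard deviations min–max normalized to [0, 1] per site (the
normalization formula is not specified by its source; min–max is our
choice, with constant rows mapped to 0). Hierarchical clustering of the
normalized-SD matrix is presentation-only (average linkage, Euclidean).

# Population structure

Bray–Curtis dissimilarity on the binary presence matrix (via
`vegan::vegdist`), classical-scaling PCOA implemented in-package
(double-centering plus a dense symmetric eigen-decomposition,
cross-checked in the tests against an independent implementation to
1e-8). Percent variance divides each eigenvalue by the sum of *positive*
eigenvalues — Bray–Curtis is semi-metric and can produce negative
eigenvalues, which would make "all axes" ill-defined. Axis signs are
arbitrary; tests assert cluster separation, never signs.

FST uses the Weir–Cockerham (1984) variance components $a$, $b$, $c$ per
locus with $\hat\theta = \sum a / \sum(a+b+c)$, computed pairwise on
diploid dosages with per-locus exclusion of missing genotypes and of loci
monomorphic across the pair. Because the original analysis fed a presence
matrix to its FST tool and the allele coding is not recoverable, a
haploid-like mode (presence as one allele per sample) is provided and
flagged in the output; the diploid mode is the default and the one the
acceptance checks calibrate ($\theta \in \{0, 0.05, 0.1, 0.2\}$
rank-order, recovery of $\theta = 0.10$ within [0.08, 0.12] at 10,000
loci). The locus subset mirrors the documented procedure: up to 10,000
loci with carrier frequency strictly above 10%, sampled uniformly under
the run seed.

# Numerical choices and problem sizes

Missing genotypes count as absence in the presence matrix but are NA in
dosages (presence mirrors the binary matrix construction; allele-count
statistics need true counts). Internal coordinates are 0-based half-open;
VCF I/O converts. Insertions occupy a single anchor base for genomic
intersections but use their full length in size computations. All
randomness flows through explicit seeds; fixed seeds give byte-identical
outputs, which the pipeline test asserts on its summary JSON.

The shipped test and acceptance workloads use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: a 2 × 600 kb
(tests: up to 2 × 1.5 Mb) reference, cohorts of 50 diploids, 500 planted
variants per class for classification recovery, 10,000 loci for FST,
5,000 null simulations for ANOVA calibration, and 200 diploid STR sites
for genotyping recovery.

# Known limitations

The built-in detectors are not drop-in replacements for wraparound-DP
tandem finding or cross_match-scored masking: they are indel-intolerant
and scan a single consensus per family. Insertion "reciprocal overlap" is
a definitional extension (size ratio with a breakpoint gate). The merge is
single-linkage and can chain through intermediate records in dense
regions. Multi-allelic records, breakends and inversions are out of
scope; the classifier handles INS/DEL sequence context only.
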