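---
title: "Linkage-map-anchored subgenome phylogenetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage-map-anchored subgenome phylogenetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(homeolink)
```

## The problem

An allo-octoploid genome carries four subgenomes contributed by distinct
diploid ancestors. Because the homeologous copies are similar, shotgun
reads from all eight chromosomes of a homeologous group pile up at the
same place in a diploid reference assembly, and conventional variant
callers cannot separate the copies. `homeolink` implements a
linkage-map-anchored strategy for octoploid strawberry-like genomes: it
exploits the fact that in an F1 cross a variant heterozygous at a *single
homeolog* of one parent appears at roughly one-eighth allele frequency in
that parent's capture reads, segregates 1:1 in the progeny, and therefore
behaves as an ordinary testcross marker that identifies its homeolog.
Everything downstream — linkage groups, subgenome phylogenies,
introgression and rearrangement scans — is built on these "LG SNPs".

## Genotype calling and LG SNP selection

Per sample and site, the caller works on raw A/C/G/T counts from an
mpileup stream (indels, read start/end marks and ambiguity codes are
consumed without contributing; depth is the count of unambiguous base
calls):

* depth < 32 → missing;
* rare variant seen ≥ 2 times at ≥ 2.5% frequency → heterozygous;
* no rare variant, or a single copy at < 1.25% frequency (treated as one
  sequencing error) → homozygous;
* anything in between → missing (ambiguous evidence).

Frequency comparisons are done in integer arithmetic
(`count * 10000` vs `depth * 250` and `depth * 125`), so the 2.5%/1.25%
boundaries behave exactly; a site whose two rarest non-major alleles tie
is coded missing because the model assumes a biallelic rare variant. No
base- or mapping-quality filtering is applied; an optional minimum base
quality is off by default.

Sites heterozygous in exactly one parent are retained as LG SNPs when
both progeny classes (heterozygous and homozygous) are observed in at
least eight progeny and at most one progeny is missing. Sites
heterozygous in both parents are set aside: they are never mapped, but
the regions they fall in are used to pair corresponding maternal and
paternal linkage groups by maximum-weight bipartite matching
(`igraph`). Adjacent SNPs closer than 1 kb chain into one "region"
(single linkage; a gap of exactly 1 kb starts a new region), matching
the footprint of one capture probe set.

Note a consequence of the exact thresholds worth knowing when simulating:
at depths ≤ 80 a *single* error read already lifts the minor frequency to
≥ 1.25%, making the sample missing rather than homozygous. With realistic
error rates this costs recall through the ≤ 1-missing-progeny filter —
the price of a deliberately conservative threshold caller — while
precision stays at essentially 1. The package's recovery tests therefore
assert the ≥ 95% recall property at error rate 0, and assert precision
and the absence of false downstream signal under noise.

## Linkage groups

Pairwise two-point statistics for the testcross configuration use the
phase minimising the recombination fraction: with `k` matches out of `n`
pairwise-complete progeny, `rf = (n-k)/n` (clamped to `[1e-6, 0.5]`) and
`LOD = k log10(2(1-rf)) + (n-k) log10(2 rf)`. Missing genotypes are
handled by pairwise deletion. Groups form by single-linkage transitive
closure at LOD ≥ 5; within a group, markers are ordered by greedy
nearest-neighbour seriation on rf (ties broken by reference position,
chains started at the marker with the largest mean rf), distances are
converted to cM with the Kosambi function `d = 25 ln((1+2r)/(1-2r))`
(Haldane available as an option), and chains are cut at gaps > 33 cM.
Pieces from the same LOD cluster that share a primary reference
chromosome are rejoined automatically and each join is logged — a
deterministic, auditable stand-in for curation by visual inspection.
Groups with fewer than five LG SNPs are "minor" and excluded from
downstream analysis. Each group is assigned the reference chromosome
carrying the majority of its markers (ties flagged and broken toward the
smaller index) and named `Species-Numeral-Subgenome-parent`, e.g.
`Fvirg-IV-Av-p`.

## Read-anchored phylogenetic markers

An LG SNP's minor allele tags one homeolog, so reads that carry it are a
haplotype sample of that homeolog. For every variant site within one
read length (default 100 bp, the probe oligo length) of an LG SNP, the
base assigned to the LG SNP's linkage group is the strict-majority
consensus of minor-allele reads covering the site; an exact tie yields
missing data, and a single qualifying read suffices by default (a
`min_support` parameter is available for noisy data). LG SNP sites
themselves are never used as phylogenetic markers — their minor variant
is private to one subgenome and carries no interhomeolog signal. The
resulting taxon-by-site matrices (linkage groups plus the two ingroup
diploids and an outgroup, one matrix per haploid chromosome) are mostly
missing by construction — only groups with a nearby LG SNP have data at
any site — and are exported in relaxed PHYLIP for external
maximum-likelihood analysis.

Internally, trees come from neighbor joining (`ape::nj`) on p-distances
with pairwise deletion; taxon pairs with no shared sites receive the
maximum observed distance and are flagged. Labels follow the clade
rules: the group inside the minimal clade holding the vesca-like diploid
(excluding the iinumae-like one) is `Av`; among the rest, the group
sister to the iinumae-like diploid is `Bi`; of the final two, the one
with the greater mean p-distance to the iinumae-like diploid is `B1`
(ties flagged, broken by group id). Inconsistent topologies yield
`unresolved`, never a guess.

## Introgression scan

At sites where a subgenome, both ingroup diploids and an outgroup all
have bases, only two-state 2:2 patterns are informative: phylogenetic
support (subgenome with its sister), introgression-like homoplasy
(subgenome with the wrong ingroup species while its sister matches the
outgroup) and outgroup homoplasy (subgenome with the outgroup). Absent
gene flow the two homoplasy classes arise from the same noise processes
and should be equally frequent; the excess test is an exact two-sided
binomial against 0.5 (a Fisher variant against a rounded 50:50 row is
reported alongside, since the published analysis quotes a Fisher test
without stating its second row).

Regions classify per parental map (conflicted regions with both
supportive and introgression-like sites are "support/homoplasy" and count
on the supportive side); per-map calls pool conservatively across maps.
Clusters are maximal windows along a chromosome that start and end at
introgression-like regions, contain at least two of them, and have an
introgression:supportive ratio ≥ 4 (zero supportive regions always
qualifies; outgroup-homoplasy regions are neutral). The window rule is
not fully pinned down in prose anywhere, so the package ships the
exhaustive window enumerator (`detect_clusters_bruteforce()`) as the
reference implementation and tests the fast scanner against it
exhaustively on short tracks. Cluster intervals run from first to last
member marker site; this convention reproduces the published span
statistics (2–1,579 kb, median 160 kb, mean 324 kb, union 15.0 Mb,
cross-subgenome overlap 604 kb over three instances) from the published
cluster table exactly. Directionality is tested by Fisher's exact test
of the observed toward-vesca/toward-iinumae cluster split against the
rounded 3:1 expectation (three iinumae-like subgenomes versus one
vesca-like). Allele-depth corroboration keeps diagnostic SNPs with
combined parental depth in [45, 200] and vesca:iinumae ratio in
[1/8, 8], averages ratios in 1-Mb bins, and compares in-cluster versus
out-of-cluster sites with a Welch t test.

## Rearrangement scan

An interchromosomal rearrangement is an LG SNP whose linkage group
belongs to a different reference chromosome. Events within 1 kb of a
capture target form the restricted set used for inference. The
clustering null distributes the observed number of events independently
and uniformly among all targeted regions carrying LG SNPs (10,000
replicates by default; a without-replacement variant is provided for
sensitivity) and records per replicate the number of regions with ≥ 2
events and the mean per-event co-occupancy; intervals are empirical
2.5/97.5 percentiles. For (105 events, 2,598 regions) the analytic
expectations are ≈ 2.05 regions with multiple events and a mean
co-occupancy of 104/2598 ≈ 0.040, which the permutation reproduces.
Copy-number corroboration normalises each sample's central-site depths
to sum to one, forms the octoploid:diploid ratio per region, and
compares rearranged versus other regions with a Welch t test. In-silico
PCR placement requires the forward primer and the reverse-complemented
reverse primer to match opposite strands facing inward with 3' ends
within 2 kb; matching is exact by default with an allowed-mismatch
parameter (the original analysis used BLAT's tolerant defaults, so exact
matching is a documented simplification).

## Scaffold ordering

Anchored scaffolds are placed on the chromosome of their linkage group
and stably reordered by median anchor cM among the slots they occupied,
so unanchored scaffolds keep their prior placement — prior order wins
wherever the maps are silent. Orientation flips when within-scaffold
anchor order is anticorrelated with cM (≥ 2 anchors); single-anchor
scaffolds keep the prior forward orientation. A scaffold anchored to two
linkage groups splits at the midpoint between the conflicting anchors
(the original analysis placed such splits with guidance from a related
genome; the midpoint is the package's deterministic, logged choice).
Scaffolds are separated by fixed 10-kb N gaps. Synteny stretches are
maximal runs of identical partner-chromosome labels along the focal
assembly — internal order shuffling does not break a run.

## The simulator

The synthetic experiment embodies the two-step allopolyploid history: a
vesca-like × iinumae-like allotetraploid (Av + Bi) later joined by an
iinumae-like autotetraploid (B1 + B2). Equal-rate (Jukes–Cantor-like)
substitutions are placed independently along each branch of the fixed
topology `((vesca, Av), (iinumae, Bi), B1, B2)` plus a distant outgroup;
base identity partitions are all the downstream logic uses, so a richer
substitution model would add nothing. Default branch rates
(substitutions/site) are `outgroup` 0.04, `vesca_clade` 0.012, `b_clade`
0.010, `bi_clade` 0.008, tips 0.005 with the B1 tip at 0.010 — chosen
once as congeneric-scale divergences that give the B1/B2 criterion
measurable signal. Introgression is wholesale tract replacement (the
package is agnostic between pre-polyploidization hybridization and
homeologous exchange, as the data cannot separate them); transpositions
are copy-and-paste duplications of a target-spanning donor segment into
another chromosome, fixed in both parents (inflating donor-region depth)
with one diagnostic heterozygous variant injected on a single acceptor
haplotype so the event is detectable as a rearrangement. Parents carry
injected single-subgenome heterozygosity at rate 0.002/site by default;
the F1 cross is strictly disomic with Poisson crossovers at uniform
positions. Capture is modeled as reads drawn uniformly among an
individual's sequence copies over windows centred on evenly spaced
targets (depth scales with copy number; eight copies is the octoploid
baseline), with independent per-base errors; a marginally equivalent
per-site count path serves the calling stages and a full read path
serves marker anchoring. The reference coordinate system is the
ancestral root sequence; only coordinates and reference bases come from
it, every comparison uses taxon bases.

What the simulator does **not** emulate: capture-efficiency bias, indels,
paralogous mis-mapping, base-quality structure and polysomic inheritance.
Passing tests therefore demonstrate the pipeline's logic and its
behaviour under idealised noise, not performance on real libraries.

## Test-scale choices

The defaults above (7 chromosomes × 1 Mb, 300 targets/chromosome, 48
progeny, depth 80, error 0.2%) describe the full study conditions. The
package's end-to-end tests run a smaller configuration chosen as the
package's own desk-scale study — 2 chromosomes × 120 kb, 70
targets/chromosome, 42 progeny, depth 70, heterozygosity 0.004,
0.5 crossovers/chromosome, four 8-kb tracts, two transpositions — which
preserves marker density per centimorgan (the quantity that matters for
grouping) while keeping runtime modest. Recovery is asserted against
planted sites that are genuinely single-subgenome heterozygous and
observable (inside a capture window, not colliding with another injected
variant or a fixed interhomeolog difference); at zero sequencing error
recall exceeds 95% with precision ≈ 1, all 16 major groups are recovered
and labeled correctly, all planted tracts are detected as clusters with
none on Av, and both planted transpositions are recovered. The
rearrangement permutation in tests uses 200–10,000 replicates depending
on the assertion's precision needs.

## Numerical conventions and degenerate inputs

Coordinates are 1-based closed throughout; BED input/output converts at
the boundary. Recombination fractions are clamped to `[1e-6, 0.5]`
before the LOD evaluation, so identical markers yield a finite LOD of
`n·log10 2`. Cluster spans are `end − start` in bp, matching the usual
kb presentation of marker-site intervals; interval unions and overlaps
use the same convention. Zero-depth pileup columns, empty linkage
groups, fewer than three taxa for a tree, both-zero homoplasy counts and
zero-denominator depth ratios are all explicit no-call or error paths
rather than silent NaNs. Every non-deterministic routine takes or
derives from a single seed, and rerunning any stage with the same seed
and inputs is bit-reproducible.
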