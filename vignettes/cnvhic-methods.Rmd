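---
title: "Methods: CNV-aware and haplotype-resolved Hi-C analysis"
author: "cnvhic"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: CNV-aware and haplotype-resolved Hi-C analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cnvhic` studies how a heterozygous multi-megabase deletion — the kind that
causes 22q11.2 deletion syndrome (about 3 Mbp lost from one copy of
chromosome 22q) or the 1q21.1 deletion — reshapes three-dimensional genome
organisation, and how those changes propagate to histone marks, gene
expression, and physical distances measured by 3D FISH. The package
implements the full computational chain: read-pair filtering and binning,
depth normalization and group fold-change maps, haplotype-resolved contact
maps built from phased SNVs, A/B compartment and topological-domain calling,
differential trans-contact statistics with permutation controls, and the
RNA/ChIP/ASE/FISH integration statistics. Everything is exercised end to end
on a synthetic diploid cohort with known ground truth.

# The synthetic cohort

## Contact model

Within one haplotype of one chromosome, the expected count between bins $i$
and $j$ at separation $s$ bins (on that haplotype's own coordinate frame) is

$$\lambda_{ij} = C\, \max(s,1)^{-\alpha}\; \kappa^{\pm 1}\; \tau^{[i,j\ \text{same domain}]}$$

where $C$ (`cis_scale`, default 15 at the 40-kbp simulation grid) sets the
depth, $\alpha$ (`decay_exponent`, default 1.0) is the distance-decay
exponent, $\kappa$ (`compartment_strength`, default 2; $\kappa$ if the two
bins share a compartment label, $1/\kappa$ otherwise) encodes the A/B
checkerboard, and $\tau$ (`tad_strength`, default 3) the within-domain
enrichment. Compartments alternate in 2.5-Mbp blocks; domains are 1.6-Mbp
tiles. Counts are Poisson and each count is materialized as a read pair at a
uniform integer position within its bin. Trans contacts have a constant rate
$\lambda_t$ (`trans_rate`, default 0.06 per 40-kbp bin pair per haplotype).
No published decay exponent exists for these data; 1.0 is the conventional
choice in the fractal-globule range, and only relative contrasts matter
downstream.

The defining design choice is that the deleted homolog is simulated **on its
own, shorter frame**: H1 of a deletion sample is a 47-Mbp chromosome, its
bins are mapped back to reference coordinates only when read positions are
emitted. Consequently the deletion bins emit nothing, loci flanking the
deletion sit $L = 3$ Mbp closer together, and the increased flank-to-flank
contact — the hallmark pattern in the real data — is an *emergent
prediction* of the geometry, not an injected effect. The expected
deleted/intact ratio at reference separation $d$ is $(d/(d-L))^{\alpha}$,
which the tests verify within 25%.

Two "hotspots" are injected as labelled synthetic constructs: a trans
contact (chr22s 30–30.5 Mbp × decoyA 3–3.5 Mbp) with a 4-fold constitutive
baseline in every sample and a further 3-fold gain in deletion samples, and
a cis partner window (21.5–22 × 45–45.5 Mbp, 2.5-fold in deletion samples)
for the anchored window ranking. The baseline factor reflects the
observation that differential trans contacts are detectable only among
constitutively strong contacts: with 5 vs 6 samples and a fixed $10^{-4}$
threshold the Welch $t$ test has 90%+ power at roughly 50 expected counts
per 500-kbp trans cell, and a uniform background at that level would be
unrealistically strong relative to cis.

## Depth

Default depth is about 1.4 million read pairs per sample, which keeps a
full cohort simulation plus binning under two minutes and gives the
500-kbp group contrasts per-cell counts in the tens-to-hundreds range. The
homolog-resolved analyses instead use a "capture-style" patient — the
target chromosome only, `cis_scale = 150` — because only ~19% of pairs are
haplotype-assignable at realistic SNV density (1 per kbp, read length
101 bp) and the real experiment deliberately deepened coverage over the
target chromosome by hybridization capture for exactly this reason.

## SNVs, reads, and haplotype truth

Phased heterozygous SNVs are uniform at `snv_density` (default $10^{-3}$
per bp, the human heterozygosity scale) on the reference frame; the deleted
haplotype simply never produces reads covering them inside the deletion.
Every emitted read knows its true haplotype; a read covering a SNV carries
that haplotype's allele. Assignment is therefore error-free by
construction, and the tests demand 100% accuracy and zero conflicts — the
machinery, not the biology, is under test. Sequencing errors, allele
dropout and mapping bias are *not* modelled, so passing tests bound only
algorithmic correctness, not robustness to noisy allele observations.

## Restriction fragments and filters

Fragments are regular 400-bp tiles (a 4-bp cutter scale). Read pairs pass
the standard Hi-C filters: exact duplicates, self-ligations (both ends on
one fragment), and in standard mode pairs whose summed distances to the
nearest restriction site exceed the library fragment length (500 bp);
haplotype mode instead removes ends farther than 1.5× the fragment length
from a site and same-chromosome pairs spanning less than 1.5× the fragment
length. With uniform positions and 400-bp fragments the distance filter is
nearly neutral on simulated data; dedicated fixtures exercise every rule.

## ChIP, expression, ASE, FISH

Peak and gene tables share one layout so that coupling is a generative
truth: genes are placed with a 2.2:1 preference for A compartments (the
same gene-density track orients the compartment eigenvector); 60% of genes
own a TSS-proximal H3K27ac peak (within ±0.8 kbp) and an H3K27me3 peak
(within ±4.5 kbp). Log2-scale effects in deletion samples: −1 for peaks and
genes inside the deletion (heterozygous halving), reciprocal ∓0.8 for
flank-region H3K27ac/H3K27me3, and for differentially expressed genes the
TSS peaks move with the gene (±0.7 × gene effect, H3K27me3 opposed). A
per-gene per-sample latent factor (sd 0.25) is shared between FPKM and the
H3K27ac peak, driving the per-gene Pearson correlation analysis.
Measurement noise is log-normal (sd 0.25 log2 for expression, 0.4 for
ChIP) — within the range of cell-line replicate variability and chosen once
so that halving of a typical gene is detectable by a 5-vs-6 Welch test
after BH correction. ASE counts are binomial at 0.5 outside the deletion
and monoallelic inside it (deletion samples only). FISH distances follow
`grand mean + deletion + gender + subject + residual` on the normalized
scale (defaults 1.0, −0.2, 0.05, sd 0.07, sd 0.3), with 16–33 cells per
line; raw distances are the normalized values times the product of the two
nuclear radii so that radius normalization recovers the model scale
exactly. The subject/residual magnitudes were fixed from a power analysis
of the nested design (5 vs 6 subjects, ~25 cells each) targeting 80–90%
power at the −0.2 effect.

# Analysis methods

## Contact maps and fold changes

Matrices are COO upper triangles bound to a bin scheme (40 kbp for domain
calling, 500 kbp elsewhere). Each sample is depth-scaled to 10 million
pairs before group averaging; raw counts are retained for inclusion
filters. The deletion-vs-control contrast supports two modes: the default
`relative_log2`, $(\log_2(d+\varepsilon)-\log_2(c+\varepsilon))/\log_2(c+\varepsilon)$
— the literal reading of "(deletion−control)/control on log2-transformed
mean contacts" — and `log2_ratio`, $\log_2((d+\varepsilon)/(c+\varepsilon))$,
whose symmetric scale matches the conventional ±2 heatmap palette. The
source description is ambiguous about the order of log and ratio, so both
are provided; biology-facing tests state which they use (the halving
checks use `log2_ratio`, where a lost allele reads as −1). The pseudocount
$\varepsilon = 1$ on depth-scaled values bounds fold changes for empty
cells; `relative_log2` cells with $c+\varepsilon \le 1$ are NaN and
counted. Fragment-level bias modelling is intentionally absent: per-sample
depth scaling is the stated pre-combination step, and for group contrasts
on synthetic data (which carry no fragment-level bias) it is sufficient.

## Haplotype assignment and density equalization

A read end is H1 if every covered SNV carries the H1 allele, H2
symmetrically, `unknown` with no SNV, `conflict` otherwise. Pairs resolve
by consensus; cross-haplotype and conflicted pairs are discarded but
counted, because an excess of cross-haplotype pairs across a genomic
boundary is the signature of a phasing switch. The switch detector
therefore compares cross vs concordant calls **among pairs spanning each
window boundary** — under power-law decay short-range concordant pairs
dominate every window, so a per-window fraction test could never fire; the
spanning-pair form applies the same "intra-chromosomal contacts should be
predominantly intra-homolog" logic to exactly the informative pairs.

To compare contacts involving the deletion region at equal footing with
the rest of the chromosome, the expected number of phased SNVs in the
region is computed from the off-region density,
`round(region_length × n_outside/(chrom_length − region_length))`, that
many distinct single-bp positions are drawn uniformly (without
replacement, seeded), and a region-involving contact is retained when at
least one region endpoint's read overlaps a sampled position. The
at-least-one rule is deliberate: requiring every region endpoint would
square the thinning for region×region contacts and distort the local
pattern. Ten replicates are drawn; reported matrices default to the
replicate mean, and stability is quantified as the leave-one-out Spearman
correlation of each replicate's 1-Mbp region-contact profile against the
consensus of the other nine (≥ 0.9 at capture depth). Equalization is
applied to both homologs alike — the source is silent on which homolog it
applied to, and symmetry is the only choice that does not bias the
difference map.

## Compartments and domains

The cis matrix is converted to observed/expected by per-separation means
over unmasked bins; all-zero rows and (on deleted homologs) deletion bins
are masked as NaN rather than zero-filled, because a zero-filled deletion
masquerades as a B-compartment flip. The leading eigenvector of the
Pearson correlation matrix of O/E columns gives compartments; its sign is
oriented by a gene-density track (gene-rich = A), since eigenvectors have
no intrinsic sign. The directionality index uses the classical form
$\mathrm{DI} = \mathrm{sign}(B-A)\left[(A-E)^2/E + (B-E)^2/E\right]$,
$E=(A+B)/2$, with a 2-Mbp window at 40-kbp bins (the window is the cited
method's convention and is exposed as a parameter). Domains come from a
penalized three-state segmentation of DI (downstream-biased / none /
upstream-biased; per-bin score $\pm z$, robust-scaled, state changes cost
10 z-units; exact dynamic program, deterministic ties): a domain opens at a
downstream-biased run and closes at the end of the following
upstream-biased run; domains under 200 kbp are dropped. This replaces the
published mixture-HMM with a transparent equivalent — the tested contract
is boundary accuracy (≥ 90% of true boundaries within ±1 bin at default
depth), not model identity.

## Differential trans contacts

All inter-chromosomal bin pairs with at least one raw read pair in every
sample are tested by the two-sided unequal-variance (Welch) $t$ test on
depth-scaled values — the default behaviour of the `t.test` function that
the original analysis called — at a fixed $10^{-4}$ threshold with no
multiplicity correction (a BH column is provided for reuse). "Strongest"
contacts are ranked by the mean depth-scaled value across all samples
(undefined in the source; the all-sample mean is the choice that is
invariant to group labels), and enrichment of significant pairs in the top
5% is tested by an exact two-sided Fisher test implemented by
hypergeometric enumeration with the standard $1+10^{-7}$ tie tolerance.
Controls: 10 seeded permutations of the deletion/control labels, and 3
random splits within each group.

## Integration statistics

Per-mark log2 fold changes of normalized counts (pseudocount 1) are
standardized to Z-scores across sites; |Z| > 2 flags differential sites
for the regional enrichment, while the TSS-side analyses use the
per-mark cutoffs 1 (H3K27ac) and 2 (H3K27me3) — the inconsistency between
the two conventions in the source is preserved as configuration, not
resolved. Regional enrichment tests each 500-kbp bin's flagged/unflagged
counts against the rest of the genome by Fisher's exact test with BH
across non-empty bins. Sites map to their nearest TSS by midpoint distance
(signed by strand), one site per gene, within ±1 kbp (H3K27ac) or ±5 kbp
(H3K27me3). The four-group coupling test compares significantly vs
non-significantly up- (and down-) regulated genes on any per-gene value by
a permutation test with 9999 permutations and the add-one two-sided
estimator $p = (1 + \#\{|T^\ast| \ge |T|\})/(n+1)$ — never zero, valid by
construction. The direct correlation analysis computes per-gene Pearson
$r$ between FPKM and TSS-site counts across shared samples, builds a
background by permuting each gene's FPKM ten times, and compares observed
vs background by a two-sided Wilcoxon rank-sum test; genes with constant
vectors are excluded and counted. ASE uses the exact binomial test of each
SNV's alternative-allele count against the per-sample mean alternative
frequency, restricted to coverage > 10.

## FISH model

Distances are normalized by the product of the shortest and longest
nuclear radius ("multiple of the radii" read as the product; a
geometric-mean option exists). The nested ANOVA is computed on subject
means: the Deletion (and Gender) $F$ test from a linear model on the 11
subject means is exactly the expected-mean-squares test of a group effect
against between-subject variation, is deterministic and oracle-checkable
against `aov` error strata, and makes cell-level pseudoreplication
impossible by construction. The cell-level residual mean square is
reported alongside. Calibration (type-I 0.05 ± 0.02 over 500 null
simulations) and power (≥ 0.8 at the −0.2 effect with 5 vs 6 subjects × 25
cells) are part of the test suite.

# Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open; `.pairs` and variant files are
1-based on disk. A position exactly at a restriction cut belongs to the
right-hand fragment (any consistent rule works; this one is documented and
tested). Pairs are mate-ordered on ingestion. Zero-variance cells are
excluded from $t$ tests with a counted reason; degenerate 2×2 margins give
$p = 1$; `DI = 0` where upstream and downstream sums are equal, including
both-zero; eigendecomposition of a constant matrix raises "no compartment
signal"; depth-normalizing an already normalized matrix is an error rather
than a silent no-op.

# Problem sizes

Default analyses run on a 50-Mbp chromosome plus two 8-Mbp decoys: 100/1250
bins at 500/40 kbp, ~1.4 M pairs per sample, ~15 M pairs per cohort. The
capture patient uses ~10 M pairs on the target chromosome alone. The
domain-recovery and calibration studies use a single 20-Mbp chromosome;
the power study for trans hotspots uses 20 replicate cohorts on a
10 + 4 Mbp genome. These sizes were chosen so the full simulation-to-result
chain stays interactive while every statistic retains the sample sizes
(5 deletion vs 6 control lines) of the study design.

# Known limitations

* The generator is uniform where real genomes are not: no mappability or
  GC structure, no fragment-length bias, no translocations or
  duplications (the deletion is the only CNV type).
* Haplotype tags are error-free; robustness to miscalled alleles is out of
  scope.
* The compartment checkerboard and regular domain tiling are idealized;
  accuracy numbers on them bound algorithmic recovery, not performance on
  real chromatin.
* The DE stand-in is a Welch test on log2(FPKM+1), plumbing for the
  enrichment and coupling analyses — not a replacement for a count-based
  RNA-seq model.
* Matrix balancing beyond per-sample depth scaling is not implemented; on
  CNV genomes balancing must mask deletion bins first, and the package's
  masking conventions (NaN, never zero-fill) exist to keep that pitfall
  visible.
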