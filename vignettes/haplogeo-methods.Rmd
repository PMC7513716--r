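---
title: "Methods: typing, diversity and origin inference for atp6-orf79-like structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typing, diversity and origin inference for atp6-orf79-like structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogeo)
```

## The problem

Gametophytic cytoplasmic male sterility (CMS) in rice is mostly conferred by
mitochondrial chimeric ORFs homologous to *orf79*, co-transcribed with the
upstream *atp6* gene as *atp6*-*orf79*-like structures. Population surveys of
wild (*Oryza rufipogon*) and cultivated (*O. sativa*) rice describe these
structures as 16 haplotypes (H1--H16) falling into four groups
(AO-I--AO-IV), carried by a minority of accessions, with strongly
structured geography. `haplogeo` implements the analysis stack such a survey
needs: typing a candidate sequence into segments and haplotypes, frequency
and diversity statistics, median-joining haplotype networks, geographic
summaries, and a genetic--spatial regression that scans candidate origin
coordinates for a haplotype.

## Reference panel and coordinate system

All positions are 1-based on the reference haplotype's (H1) coordinate
system, with closed intervals; the structure spans `atp6` 1--1005, a
flanking segment (fs) 1006--1115, an intergenic noncoding segment (ncs)
1116--1221 and the `orf79` CDS 1222--1461. The packaged variant matrix
(23 loci: 18 SNPs, 3 block substitutions, 2 small insertions across 16
haplotypes) fully determines every haplotype's states. The panel's
sequences are *synthesised* from this matrix on a synthetic template: the
variant states are the published ones, while invariant positions and the
interior of the heterologous blocks are deterministic random filler. This
affects nothing the package computes from the panel -- typing compares
states at the variant loci, distances and networks use only the variable
columns -- but it means the absolute sequences are not the deposited ones,
and alignments against real data should use genuinely assembled sequences
as the panel (`build_sequences_from_variant_table()` accepts a real block
library).

One subtlety: the SNP at position 1063 lies *inside* the fs block
substitution window (1011--1115). It exists only in the coordinate frame of
the reference-length (105 bp) block; haplotypes carrying the 49 bp fs2
block take the reference state at that locus by convention, both in
synthesis and in typing.

## Structure typing

`decompose_structure()` anchors the query on the 1005 bp *atp6* segment by
semi-global alignment (affine gaps, match 2 / mismatch -3 / gap open 8 /
extend 2) and requires 95% identity -- the gene is reported invariant in
these panels, so a high threshold is safe; reverse-complement queries are
detected by running the anchor on both strands. The query is then mapped
onto the closest panel haplotype, and the per-locus states are read off
through that alignment:

* **fs**: the block length (105 vs 49 bp) plus the diagnostic SNPs at
  1008 (T = fs1, A = fs2) and 1063 (C = fs1a, G = fs1b). When the block is
  truncated by the query, the SNPs alone decide the subtype.
* **ncs**: exact match of all ncs-region states against the panel; an
  unmatched pattern falls back to the block-length family (45 bp = ncs1,
  46/55 = ncs2, 51/53 = ncs3) and is reported `<family>-novel`. The `-SV`
  suffixed types are simply distinct state patterns in the panel.
* **orf79**: exact match of the six CDS SNPs (1225, 1234, 1363, 1367,
  1368, 1399) to an allele name; unmatched patterns are `orf79-novel`.

`classify_haplotype()` is an exact 23-locus match; anything else is
`novel`, with *all* tied nearest haplotypes reported rather than one picked
silently. `assign_group()` is the total function fs1×ncs1 → AO-I,
fs1×ncs2 → AO-II, fs1×ncs3 → AO-III, fs2×ncs1 → AO-IV, otherwise
`unclassified`. Isolate *orf79* contexts (the structure-free NA1--NA3
arrangements) are called by `detect_isolate_orf79()`: an *orf79* is
isolated iff no *atp6* CDS ends within `W` bp upstream on the same strand.
`W` defaults to 2000 bp -- the source material says only "far away", and
2 kb exceeds every intergenic gap inside the known complete structures;
the window is inclusive (a gap of exactly `W` is still adjacent).

## Population statistics

* **Frequencies** are exact rationals with display rounding matching the
  survey tables: percentages half-up to 1 decimal, regional proportions to
  2 decimals (base R `round()` is half-to-even, which does not match the
  printed tables).
* **Nucleotide diversity** is the unbiased mean pairwise per-site
  difference, `pi = 2/(n(n-1)) * sum k_ij / L_ij`; haplotype diversity is
  `n/(n-1) (1 - sum p_i^2)`. The default gap policy is pairwise deletion
  with block-substitution and insertion columns excluded from the site set
  -- their length changes are not nucleotide substitutions -- and the
  policy is recorded in every result. The original survey's site set (it
  reports an alignment of 1,485 bp) cannot be reconstructed exactly from
  the variant matrix, so published pi/FST values are context, not targets.
* **Tajima--Nei distance** is the equal-input formula
  `d = -b log(1 - p/b)` with `b = (1 - sum g_i^2 + p^2/h)/2`,
  `h = sum x_ij^2/(2 g_i g_j)`; saturated pairs return `Inf` rather than
  an arbitrary cap.
* **FST** is the Hudson-style `1 - Hw/Hb` (size-weighted mean within- vs
  between-population pairwise differences) -- the estimator computable from
  pairwise differences alone. Negative sampling estimates are clipped to 0
  and flagged; two identical monomorphic populations define FST = 0. The
  optional p-value is a seeded label-shuffling permutation test.
* **Nm** uses the haploid island model `FST = 1/(1 + 2 Nm)`, i.e.
  `Nm = (1-FST)/(2 FST)`, appropriate for a maternally inherited genome.
* **ts/tv** classifies, per SNP locus, each distinct non-ancestral state
  against the ancestral (reference haplotype) state.
* **dN/dS** is Nei--Gojobori counting: per-codon synonymous site
  fractions, equal-weight averaging over all minimal mutation paths
  between codons (changes through or into stop codons count as
  nonsynonymous), Jukes--Cantor correction, and averaging of dN and dS
  over all allele pairs (the ratio is `mean dN / mean dS`). This counting
  estimate is deliberately *not* comparable to likelihood site-model
  estimates of the same quantity.

## Median-joining network

States are categorical per locus (base, block label, insertion presence);
every state change costs one step -- including the 4 bp insertion, which is
one categorical step, not four. The algorithm builds the minimum spanning
network (an edge joins two nodes iff no strictly cheaper path connects
them; the `epsilon` parameter relaxes the threshold and defaults to 0),
then repeatedly considers the majority-consensus median of every node
triple and adds, one per pass, the median giving the largest strict
reduction in spanning cost (ties broken by lexicographic state order, so
the result is independent of input order). Loci where all three states
differ contribute no median: quasi-median expansion is not implemented,
which is a real restriction for highly multi-allelic loci but immaterial
for this panel. Finally, medians whose removal leaves the spanning cost
unchanged are pruned, so surviving medians are genuine branch points
(degree >= 3). `root_candidates()` ranks observed nodes by agreement with
supplied ancestral states, then degree, then sample size, and reports ties
explicitly.

## Geography

Distances are haversine great-circle distances on a sphere of radius
6371.0088 km (mean Earth radius); printed survey distances cannot
adjudicate sphere vs ellipsoid, and the sphere keeps every statistic
symmetric and rotation-equivariant. The geographic central feature (GCF)
is the sampled accession minimising mean distance to the others (ties go
to the lexicographically smallest id and are flagged). The geographic
median centre (GMC) is the spherical geometric median, computed by
Weiszfeld iteration in the tangent plane (the step is the
1/distance-weighted mean of the log-map images, so the fixed point
satisfies the stationarity condition of the mean-distance objective);
tolerance 1e-10 radians on the step, at most 1000 iterations, with a
0.01-degree local grid search fallback on non-convergence. Kernel density
uses `MASS::kde2d` on raw lon/lat degrees with the normal reference
bandwidth per axis -- adequate at the tropical latitudes of these panels,
distorted at high latitudes. The Mantel test is one-sided (positive
association, the isolation-by-distance hypothesis) with
`p = (1 + #{permuted r >= observed}) / (n_perm + 1)`; the permutation
machinery is `vegan::mantel`, forced to sampled permutations so the stated
convention holds at any matrix size.

## Origin inference

For a target haplotype, `y` is the vector of genetic distances from the
target to each other haplotype in the filtered set -- computed once per
scan, since it does not depend on the candidate -- and, for each candidate
origin `c`, `x_i` is the mean great-circle distance from `c` to the
carriers of haplotype `i`. An ordinary least-squares line `y = a x + b` is
fitted per candidate and the surface of `R^2` values is returned; cells
with degenerate (constant) `x` are flagged undefined and excluded from
hotspots. The hotspot is all cells with `R^2 >= 0.8` (the threshold is a
parameter), reported with its peak cell and bounding box. Design choices:

* The haplotype set comes from `filter_haplotype_set()`: group membership
  *and* at least one carrier in the requested regions, with an explicit
  extra-include list for external reference haplotypes.
* The default genetic distance is `tajima_nei_distance()` on the panel
  alignment; the function is injectable, so an externally computed
  distance vector (e.g. model-based ML distances) can be supplied.
* The default lattice is the carrier bounding box padded by 5 degrees at
  0.1-degree steps, matching the precision at which such hotspots are
  reported; each haplotype contributes one point regardless of carrier
  count (an `n_i`-weighted fit is available but off by default). No
  land/sea mask is applied.
* `surface_argmax(refine = TRUE)` polishes the peak by Nelder--Mead
  optimisation of the same `R^2` objective in continuous coordinates.
  The lattice argmax alone is biased toward whichever neighbouring cell a
  shallow ridge of the surface favours when the true optimum falls near a
  cell boundary; refinement removes that discretisation artifact from the
  reported optimum.

## The synthetic generator: what it does and does not emulate

`simulate_dispersal_panel()` realises the model the regression assumes:
one ancestral haplotype seated at the origin, derived haplotypes at focal
points drawn uniformly (default 100--1500 km from the origin, uniform
bearing), carriers scattered around each focal point along geodesics
(bearing uniform, distance `|Normal(0, 150 km)|`), and per-site genetic
distance from the ancestor `k_i/L = a x_i + b + Normal(0, noise_sd)` with
`x_i` the realised mean carrier distance and `k_i` rounded to an integer
mutation count placed without replacement (transitions:transversions 2:1,
emulating the elevated transition regime of organelle sequence data
without rate heterogeneity). Defaults: `slope_a = 5e-6` per km and
`intercept_b = 5e-4` put distances in the 1e-3--1e-2 per-site range over
the 100--1500 km focal band, the scale of the survey's distance matrices;
carrier counts are `1 + Poisson(2)`, emulating the published skew (most
haplotypes have 1--4 carriers). Everything is a pure function of the seed.

The generator does *not* emulate: multicentric origins (a single origin
per panel), founder effects or barriers, recombination or heteroplasmy
(clonal maternal inheritance), non-Gaussian residuals (the source model
states no noise model; Gaussian is this package's assumption), or real
coastline/land-mask geometry. Passing recovery tests therefore shows the
inference machinery is correct *under its own model*, not that the model
captures every feature of real survey data.

Two conditions of the packaged recovery experiment deserve explanation.
First, the noise level is scaled to the carriers' mean dispersal range,
`noise_sd = 0.2 a E|N(0, 150)| (~ 0.2 a x 120 km)`: the dispersal scatter
is the physical source of unexplained variation in the regression (the
same scale the model's intercept measures), and noise proportional to the
mean *focal* distance instead would drive the true `R^2` at the origin
down to ~0.87, a regime in which no estimator could place the origin
inside an `R^2 >= 0.8` hotspot reliably. Second, the noise-free runs use
100 kb sequences: mutation counts are integers, so per-site distances are
quantised at `1/L`; at 100 kb the quantisation (1e-5) is negligible
against the modelled distances and the noise-free construction is
collinear in a meaningful sense. `simulate_null_panel()` places carriers
uniformly in a bounding box independent of the mutation process, giving
the no-association regime used to calibrate the Mantel test's type-I
error.

## Numerical conventions and degenerate inputs

Longitudes are normalised into (-180, 180]; coordinates are WGS84 decimal
degrees (the survey states no datum; WGS84 is assumed). Seeds are
mandatory for every stochastic stage and echoed into report provenance.
Degenerate inputs fail loudly and early: inverted spans, duplicate ids,
out-of-range coordinates, constant distance matrices, populations of one,
saturated distances, haplotypes without located carriers, and origin scans
with fewer than three usable haplotypes are all explicit errors, not
silent NA propagation.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on generated data
and the packaged tables: origin recovery uses 20 seeded panels of 8
haplotypes (~24 carriers) scanned at 0.25 degrees; Mantel calibration uses
1000 null panels of 6 haplotypes with 199 permutations each at alpha =
0.05; oracle comparisons (exhaustive network search, dN/dS path
enumeration, fine-grid medians) use instances small enough to enumerate.
These sizes make every check exact or tightly bounded while keeping the
whole suite inexpensive.

## Known limitations

Typing assumes the query contains a full-length *atp6* anchor; structures
split across contigs are reported partial at best. The ncs subtype call is
an exact state match against the packaged panel, so genuinely novel
within-family variants type as `<family>-novel` rather than receiving new
names. The network's median set is majority-consensus only. KDE on raw
degrees distorts at high latitude. The counting dN/dS is a different
estimand from site-model ML values. Published pi, FST, Mantel and
GCF/GMC values for the real accession panel depend on supplementary
coordinates and sequences not packaged here; the suite validates the
machinery on synthetic panels and the published table arithmetic instead.
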