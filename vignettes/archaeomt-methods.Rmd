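---
title: "Models and methods behind archaeomt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind archaeomt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archaeomt)
```

# Scope

`archaeomt` implements an analysis chain for studying late archaic-human
population history from two kinds of evidence: partial ancient
mitochondrial genomes sequenced from damaged short DNA fragments, and
tables of dated archaeological localities. The chain runs from raw
aligned fragments to a consensus mitogenome, through dataset curation
and phylogenetic placement, to diversity comparison, clock-rate
estimation and spatiotemporal pattern tests. A synthetic-data module
generates every input the downstream stages need, so that all guarantees
can be verified without external downloads.

# Consensus calling from damaged fragments

Post-mortem cytosine deamination makes ancient DNA read as C→T near the
5' end of fragments (and, in the mirrored orientation, G→A near the
3' end). This is simultaneously the main source of miscalled bases and
the best authentication signal: present-day contaminant DNA lacks
terminal damage.

The consensus stage works on `AlignedFragment` records (1-based circular
coordinates on the 16,569-bp mtDNA reference) and applies, in order:

1. **Contamination gating.** A library whose external contamination
   point estimate is *strictly above* 10% is restricted to fragments
   showing a C→T (or G→A) mismatch within three positions of either
   fragment end; at or below 10% all fragments pass. The estimator
   itself is an input, not part of the package.
2. **Damage masking.** Every C→T or G→A mismatch against the reference,
   anywhere in the read, has its base quality set to 0, which removes it
   as evidence. Masking means exclusion rather than down-weighting
   because the goal is that no deamination product can contribute to a
   call.
3. **Quality trimming.** Up to three consecutive terminal positions with
   quality below 20 are removed from each read end. The cap is strict: a
   fourth low-quality base is retained.
4. **Consensus rule.** After removing duplicate fragments (identical
   start, end and strand — "independent fragments" means
   post-deduplication molecules), a base is called at a position when at
   least 3 fragments cover it and the modal base reaches at least 65% of
   them; otherwise the position is `N`. The 65% threshold is inclusive
   (ties at exactly 65% pass); a modal-base tie emits `N`. Masking is
   applied before agreement is computed.

With masking enabled, a damage miscoding can never be called: any
read-level C→T/G→A mismatch is excluded from the tally, so damage can at
worst turn a position into `N`. The test suite verifies this at terminal
damage rates up to 0.58, the upper end of what authentic Late
Pleistocene single-stranded libraries show.

# Curation rules

Sequences with more than 2,600 unresolved positions (below 85% of the
reference) are excluded before tree-based analyses; heavier missingness
destabilises parsimony topologies. Within an archaeological site, two
individuals are duplicates when they agree at every position resolved in
both; duplicate classes are the transitive closure of that relation
(an N-rich sequence can bridge two resolvable sequences into one class —
a deliberate, conservative consequence of the pairwise-resolved rule),
and each class keeps its least-incomplete member. For coding-region
analyses the control region is trimmed using the rCRS D-loop bounds
16,024–16,569 and 1–576 (configurable; published column counts from
other studies depend on their specific alignments and are not treated as
constants). Alignment columns can be filtered by *complete deletion*
(no unresolved base in any row) or *partial deletion* with an inclusive
per-column resolved fraction (default 0.90).

# Diagnostic-SNP placement

Incomplete genomes that would destabilise a parsimony tree are placed on
a fixed reference topology instead. For every variable alignment column,
Fitch parsimony on the rooted reference tree (polarised by a designated
outgroup tip) locates the branch on which the substitution arose.
Columns with a single origin define a diagnostic SNP for that branch's
child node; multi-origin columns are flagged homoplasic and excluded
from placement by default. Any C/T or G/A substitution is flagged
damage-susceptible regardless of strand, because a consensus may mix
fragment orientations.

Placement walks from the root: at each step the query is tallied over
each candidate child's diagnostic SNPs (derived / ancestral / missing /
conflicting, where conflicting means a third allele), descends while
derived matches strictly exceed conflicting ones with at least one
informative site, picks the child with the largest derived-minus-
conflicting margin, and stops on ties. The deepest accepted node is the
assignment; a query with no informative site at the first step is
`unresolved`. With damage-susceptible sites omitted, a deamination
miscoding cannot produce a spurious derived match: at a retained site
the derived and ancestral states are not a C/T or G/A pair, so a C→T or
G→A flip of the ancestral state yields a third allele, which counts as
conflict, never as support. This is why the simulation tests score
placement onto the true node *or any of its ancestors* as success —
omission can shorten the walk but not redirect it.

The "full" versus "tentative" confidence note is a simple flag (every
accepted step conflict-free and without ancestral matches); the
field-standard practice this mirrors is a qualitative dashed-line
annotation, so no probabilistic calibration is claimed.

# Diversity comparison

Nucleotide distances are mismatch counts over positions resolved in both
sequences (pairwise deletion). Within-site distance vectors (all
unordered pairs) are compared to the branch-wide vector with a two-sided
Wilcoxon rank-sum test: exact for tie-free samples up to n+m = 25, exact
by complete enumeration of group assignments for tied samples up to
n+m = 12 (the permutation distribution is symmetric, so the two-sided p
is the mass at least as far from the mean as observed), and the normal
approximation with continuity correction otherwise. P-values are
adjusted across sites with Benjamini–Hochberg by default; the method is
a flag because published "adjusted P" values rarely name the procedure.

# Temporal signal and molecular dating

Under a strict clock, a tip's expected distance from the root grows
linearly with elapsed time, so regressing root-to-tip distance on
negative sampling age (years BP) estimates the substitution rate as the
slope. The regression is ordinary least squares, matching the standard
temporal-signal tool; the root is an input rather than optimised,
because the upstream analyses root explicitly with an outgroup.
Molecular ages for undated tips invert the fitted line; their prediction
intervals map the distance prediction interval through the slope, an
approximation that ignores slope uncertainty in the denominator and is
therefore slightly narrow when the regression is weak. Held-out-tip
coverage of the nominal 95% intervals is checked by simulation in the
test suite. Two dated tips are accepted (exact interpolation), but
prediction intervals require three.

The default dating rate everywhere is 1.57e-8 substitutions/bp/year, the
strict-clock mitochondrial rate standard in hominin dating work.

# Spatiotemporal analysis of localities

Records whose date range exceeds 30 ky are considered too poorly dated
and excluded. A record then joins **every** 10-ky slice its range
overlaps (a record spanning 75–55 ka is evidence of presence in 80–70,
70–60 and 60–50); midpoint assignment is available for sensitivity
analysis. Slices are anchored at multiples of 10 ka and treated as
half-open `(end, start]`, so a point date of exactly 70 ka falls in the
70–60 slice.

Spatial intensity uses a Gaussian kernel with unit mass per locality and
Silverman's rule per axis by default (the bandwidth is a flag; published
maps rarely print theirs). Hotspots use the self-inclusive local
Getis–Ord Gi* statistic on gridded counts (default 1° cells, binary
weights within a 3-cell Euclidean band):

$$z_i = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
{S \sqrt{\left(n \sum_j w_{ij}^2 - W_i^2\right)/(n-1)}}$$

with $\bar X$ and $S$ the population mean and standard deviation over
all cells. A constant field is defined to have $z = 0$ everywhere. The
z-scores are validated against both direct formula evaluation and a
Monte-Carlo permutation standardisation.

**Structured permutation test.** Whether a slice's hotspot pattern could
arise from random sampling is tested by shuffling slice labels over the
pooled locality positions (preserving per-slice counts and the pooled
spatial distribution) and comparing the observed count of cells with
$|z| \ge$ a threshold (default 1.96) to its null distribution, with
add-one smoothing $p = (1 + \#\{null \ge obs\})/(reps + 1)$. Because the
null preserves pooled locations, this design is calibrated (type-I error
at the 5% level is verified over 500 null datasets) but is sensitive to
a specific alternative: slices whose concentrations are *diluted by
pooling*, i.e. hotspots that shift location between slices. A single
tight cluster against diffuse neighbours is largely invisible at the
default threshold — the null mixture inherits the cluster and typically
shows at least as many cells above 1.96 — whereas slices clustered at
distinct centres are detected with high power at a stricter threshold
(the property test uses $z \ge 5$). The threshold is exposed precisely
because this trade-off is real.

**Rarefaction of longitudinal spread.** To compare geographic spread
between unevenly sampled slices, the target slice is repeatedly
downsampled to a fixed number of unique localities (default n = 60,
1,000 replicates) and three metrics are computed per replicate: full
longitude range, central-95% range (2.5–97.5 percentile span, type-7
quantiles) and occupancy of 2° longitude bins anchored at multiples of
the bin width from −180°. Duplicated site identifiers within a slice
count once. The one-sided smoothed p-value is the proportion of
replicates at or below the baseline's metric, testing "target broader
than baseline". For a well-calibrated null comparison the baseline
should itself be a size-n sample; a larger baseline makes the test
conservative, since its observed range stochastically exceeds that of
size-n subsamples.

# The synthetic-data generators

The generators emulate the statistical structure the analysis stages
assume:

- **Trees**: a serially sampled (heterochronous) coalescent with
  constant population-size parameter, expressed directly in years; tip
  ages drawn uniformly from a configurable window. Defaults use a
  50,000-year coalescent parameter with tips on 40–120 ka, giving tree
  depths and branch lengths comparable to the Late Pleistocene hominin
  mitochondrial record (a handful of substitutions per branch at the
  default rate over 16.6 kb).
- **Sequences**: TN93 (or JC69) with a fixed invariant-site mask and a
  strict clock; transition probabilities per branch come from the matrix
  exponential of the generator scaled to one expected substitution per
  unit. The `rate` applies at non-invariant sites, so the genome-wide
  realised rate is `rate * (1 - invariant_fraction)`; simulations meant
  to recover the dating rate therefore use an invariant fraction of 0.
  Defaults `kappa1 = 20, kappa2 = 40` give the strong transition bias
  typical of mitochondrial evolution.
- **Fragments**: log-normal lengths (default mean 60 bp, sd 15 bp —
  chosen as typical for ancient DNA since source libraries rarely
  publish their length distributions), uniform circular placement,
  terminal deamination with geometric decay into the read, undamaged
  contaminant reads drawn from a second genome, and constant base
  qualities so that damage-filter logic is isolated from quality noise.
  The default terminal damage rate of 0.30 sits mid-range of the 10–58%
  observed in authentic libraries.
- **Localities**: per-slice counts, uniform or clustered longitudes of
  configurable width, a latitude band and date-range widths; counts are
  honoured exactly so downstream tests can rely on them.

Every generator is a pure function of its parameters and seed. What the
generators deliberately do **not** model: indels, recombination,
selection, sequencing error beyond deamination, spatially varying
research intensity, or radiocarbon calibration error. Passing tests on
synthetic data therefore demonstrate the correctness of the algorithms
under the stated models, not robustness to the full messiness of real
archives.

# Numerical choices and problem sizes

Thresholds follow the field's conventions: agreement is inclusive at
0.65, contamination gating strict above 0.10, partial deletion inclusive
at its fraction, p-values from permutations use add-one smoothing so
they are never 0. Circular coordinates are handled modulo 16,569
throughout with 1-based positions.

The automated checks run at sizes chosen to finish quickly while leaving
the statistics well-resolved: consensus oracle equivalence on 200 random
pileups; damage-elimination across 50 genomes of 2 kb at 20× (the
guarantee is structural, so genome length is immaterial); placement
recovery on 200 damaged, 30%-missing queries against a 20-tip reference
of full mitogenome length; clock-rate recovery over 100 replicates of 30
tips and 15 kb; hotspot calibration over 500 null datasets of 120
localities; rarefaction power over 40 datasets at the default n = 60.

# Known limitations

- Placement assumes the reference topology is correct and reports no
  likelihood-based uncertainty; it is a formalisation of manual
  diagnostic-allele inspection.
- The inverse-regression prediction intervals are first-order; for very
  weak temporal signal they undercover.
- Gi* on counts treats cells as exchangeable under permutation and
  ignores latitude distortion of cell areas; at continental scales in
  mid-latitudes this is a second-order effect relative to sampling bias.
- The hotspot permutation design cannot separate "one slice is clustered
  and the pool is too" from noise (see above); conclusions about a
  single slice's absolute clustering need a different null.
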