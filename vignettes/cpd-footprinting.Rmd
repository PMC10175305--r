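---
title: "UV damage footprinting with cpdfootprint: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UV damage footprinting with cpdfootprint: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdfootprint)
```

## The assay and the data model

UV light produces cyclobutane pyrimidine dimers (CPDs) exclusively at
dipyrimidines (diPys: TT, TC, CT, CC on one strand).  Proteins bound to DNA
inside cells locally stimulate or inhibit CPD formation at specific bases,
so deep, base-resolution CPD counts from UV-irradiated cells, compared with
counts from naked (deproteinized) DNA irradiated in vitro, act as a DNA
footprint of protein-DNA contacts.  By purine/pyrimidine complementarity
roughly 75% of genomic base pairs belong to at least one diPy on one strand
or the other, so most positions are potentially informative.

Sequencing libraries are cleaved at dimers, and the mate-1 5' end lands two
bases downstream of the dimer on the opposite strand.  `cpdfootprint`
therefore recovers each CPD from a deduplicated mate-1 alignment record as
*the two bases upstream and on the opposite strand of the mate-1 5' end*:

* a `+` record with leftmost 0-based position `p` gives the dinucleotide
  `(p - 2, p - 1)` on the `-` strand;
* a `-` record with half-open end `q` gives `(q, q + 1)` on the `+` strand.

All coordinates are 0-based half-open (BED convention) internally and on
disk; wig export is 1-based as the format requires.  The convention is
pinned by a round-trip property: the synthetic generator's
`emit_read_pairs()` is the exact inverse of `extract_cpd_positions()`
followed by the diPy filter, bit-exactly, for every valid track.  Only
detections whose reference dinucleotide is a diPy on the detection strand
are counted; everything else is tallied for QC (real libraries contain a
small percentage of such off-target detections).

Counts are held on the full diPy grid of each region (zeros included) in a
`cpd_track_set`, a light positions x samples container.  At any dinucleotide
start only one strand can carry a diPy, which makes per-position keys
unambiguous.

## The differential damage model

The emulated study design compares nine UV-exposed cellular replicates
(three untreated, three serum-starved, three serum-stimulated) against nine
naked DNA replicates, with three no-UV controls.  Per-position counts are
modeled as negative binomial with variance `mu + alpha * mu^2`; `alpha = 0`
is Poisson.  `compare_groups()` composes:

1. **Size factors** — median-of-ratios over the region's diPy positions,
   normalized to geometric mean 1.  One pseudocount is added to every count
   before ratios and tests, which keeps the geometric-mean reference finite.
2. **Dispersion** — a single per-region `alpha` by pooled method of moments
   over positions within groups, floored at 0.  No shrinkage or empirical
   Bayes: at the depths this assay targets (tens to hundreds of detections
   per diPy) the pooled estimator is stable, and per-position models are
   out of scope.
3. **Exact test** — for each position the total (pseudocounted) count is
   split between the groups; the two-sided P-value is the summed
   probability of all splits no more likely than the observed one, with the
   group-sum marginals negative binomial matched by mean and variance
   (Poisson when `alpha = 0`).  This is the classical conditional exact
   test for overdispersed counts.
4. **Raw log2 ratios** — log2 of the ratio of normalized, pseudocounted
   group means, oriented numerator/denominator (cellular/naked).
5. **Local window correction** — the per-position baseline is the log2
   ratio of the two groups' summed means over a window centered on the
   position (default 250 bp), truncated at region edges; corrected = raw -
   baseline.  This removes the smooth, locally varying (GC-linked) ratio
   bias between conditions.  The window *divides window sums* rather than
   averaging per-position ratios, and it slides per position rather than
   tiling, to avoid tile-boundary artifacts.  The span is symmetric
   (`window/2` bases each side, i.e. 251 bases in total at the default), so
   corrected profiles are exactly invariant under reverse complementation
   of the region.
6. **DiPy class normalization** — corrected ratios are centered per diPy
   class within each region, so TT, TC, CT and CC each average exactly
   zero.  This removes the class-level skew between conditions, most
   visibly elevated TT damage in naked DNA relative to cellular.
7. **BH q-values** — Benjamini-Hochberg across the region's positions.

A planted multiplicative modulation `f` at a diPy therefore appears in the
normalized profile as `log2 f` (the display scale: +4 means a 16-fold
increase), minus a small self-subtraction through the window baseline and
class means; with the default window this bias is about 2% for isolated
sites.

### Numerical behavior of the exact test

The test is exact and discrete.  Its null distribution is therefore a
conservative staircase rather than exactly uniform: at per-position totals
around 600 (3 vs 3 replicates at depth 100) the empirical false-positive
rate at 0.05 is 0.04-0.05, but a Kolmogorov-Smirnov test against the
uniform on 10,000 positions detects the staircase (D around 0.04).  This is
a property of any discrete exact test at these counts, not an estimation
artifact; a mid-P correction would pass KS but would no longer be the
summed-probability exact test, so it is deliberately not used.

## Motifs, signatures and occupancy

Each factor carries a permissive *display* motif used to enumerate
candidate sites and a stricter *classification* motif whose consensus
forces a diPy at every informative offset:

| factor | display | classification | consensus diPys (offset, strand rel. motif) |
|---|---|---|---|
| ETS | `TTCCK` | `TTCCK` | TT (0, same), TC (1, same), CC (2, same) |
| SRF/CArG | `CCW6GG` | `CCTW5GG` | CC (0, same), CT (1, same), CC (8, opposite = the trailing GG) |
| NF-Y | `CCAAT` | `CCAAT` | CC (0, same), TT (2, opposite = the central AA) |

A display-motif match whose realized sequence lacks a diPy at a required
offset (e.g. a CArG box with A in the third position) is *uninformative*
and is explicitly not classifiable — never silently zero-filled.  A site's
**signature** is the vector of class-normalized log2 ratios at its
consensus diPy keys, ordered in motif orientation (for a `-`-strand site
the first motif base is the rightmost genomic base).

Occupancy is predicted by a nearest-neighbor rule: Euclidean distance to
the closest exemplar of each class, where the neutral class always includes
the theoretical unbound site (all-zero vector, no damage modulation at any
informative position).  Exact ties are called unbound — the conservative
choice, since a bound call asserts a positive finding.  Exemplars are
user-supplied; the shipped defaults are the synthetic generator's own
signature templates (log2 of the planted modulation factors) and are
labeled synthetic: they emulate the direction and scale of real footprints
but are not measured values.

For sparse genome-wide data, `aggregate` sums detections over many sites
instead: bound sites are motif matches inside both ChIP-derived site calls
and accessibility peaks; unbound sites are matches with no overlap with the
exclusion sets or accessible chromatin, down-sampled to 10x the bound
count.  Counts per motif offset are depth-normalized per condition and
adjusted by per-class correction factors chosen so the genome-wide
four-class frequency distributions agree between conditions.  The common
target distribution is the pooled (count-weighted) one; any common target
satisfies the published constraint and the resulting log2 ratios are
invariant to the choice, which the tests verify.  Offsets where a realized
site has no diPy contribute no counts, and the aggregate motifs are the
stricter non-degenerate ones (`CCTTW4GG`, `YYTTCCK`, `CCAAT`).

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes — it is the test bed, not a model of the chemistry.  Defaults
describe promoter-scale targets and deep coverage:

* **Counts**: NB with `variance = mu + alpha * mu^2`;
  `mu = depth * copy_number * bias(pos) * class_rate(diPy, condition) *
  modulation(pos, condition)`.  `depth` is the expected detections per diPy
  at class rate 1 (default 100, matching tens-to-hundreds of detections per
  site).
* **Class rates**: TT-dominated, with the naked TT rate elevated relative
  to cellular (1.3 vs 1.0) — the skew that class normalization must remove.
  The remaining rates (TC 0.5-0.55, CT 0.30, CC 0.35) reproduce the
  qualitative class ordering of deep CPD data.
* **Dispersion**: `alpha = 0.01`.  Replicates of this assay are tight —
  the dominant replicate-to-replicate differences are library size (handled
  by size factors, emulated by a lognormal depth jitter of sd 0.1) — so a
  small residual overdispersion (about 10% extra coefficient of variation at
  high depth) is the realistic regime.
* **Bias**: an exponentiated, kernel-smoothed Gaussian walk per condition
  class (correlation length 500 bases, log-sd 0.2), mean-normalized to 1.
  Because cellular and naked get independent fields, the cell/naked ratio
  carries exactly the kind of smooth local bias the 250-bp correction is
  designed to remove.
* **Planted sites**: non-overlapping motif realizations with per-offset
  modulation factors in cellular samples only (naked and no-UV samples are
  never modulated).  Bound-site templates follow the observed directions:
  ETS stimulates at TT/TC and strongly (16x) at CC; SRF stimulates the
  leading CC and CT and protects the trailing diPy; NF-Y inhibits the
  leading CC and strongly stimulates the TT opposite the central AA.
  Overlap requests are an error, never silently resolved.  The default
  spacing between planted sites (250 bases) keeps each site's window
  baseline dominated by background; real promoters can cluster sites more
  tightly, in which case the window correction partially absorbs shared
  signal — a known property of the windowed method, not of the generator.
* **No-UV controls**: the background rate is configurable
  (default 0.5% of depth) since only "few detections" is known about it;
  `non_dipy_rate` (default 1%) plants detections at non-diPy positions to
  exercise the filter QC path.
* **Boundary handling**: the first `+`-strand and last `-`-strand diPy of a
  region cannot be encoded as mate-1 records, so the generator assigns them
  zero rate; `emit_read_pairs()` raises an error on any other unencodable
  detection.

Everything is seed-deterministic: one config seed drives sequence,
planting, and counts through derived sub-seeds.

What the generator does **not** emulate: capture hybridization efficiency,
PCR duplication, sequencing error, mappability, repair kinetics, or
sequence-dependent photochemistry beyond the four class rates.  Passing
tests on simulated data therefore demonstrate the correctness and
calibration of the statistical machinery under the assumed model, not the
biological accuracy of any particular real-data estimate.

## Problem sizes used in validation

The test suite and the acceptance script validate at the following scales,
chosen to make the estimators' sampling noise small relative to the
assertions: diPy coverage on a 1 Mb random sequence; round-trip exactness
over 100 random generator configurations; null calibration on ~10,000 diPy
positions (20 kb region), 3 vs 3 replicates at depth 100; recovery of
modulation factors 4/8/16 from 6 planted sites each (12 kb region, depth
200, 9 cellular vs 9 naked) where recovery is assessed as the mean
normalized log2 ratio over a factor's planted sites; and occupancy
classification of 100 bound plus 100 unbound sites (66 kb region, depth
100).

## Other design choices

* **PCA of count vectors** (`pca_samples()`): samples are depth-normalized
  within the region, transformed `log2(x + 1)`, centered per position, and
  decomposed by SVD; each component's sign is fixed so its largest loading
  is positive.  The transform is this package's choice; a raw-count PCA
  would be dominated by the deepest positions.
* **Windowed overviews** (`window_extrema()`): non-overlapping 25-bp tiles
  from the region start (last partial tile included) reporting max, min and
  the signed maximum-absolute normalized log2 ratio, so stimulation and
  protection are weighted equally.
* **qPCR** (`qpcr_relative_expression()`): technical duplicates are
  averaged on the Ct scale before linearization `2^-(dCt)` — the order of
  averaging is this package's choice — then scaled so the baseline
  condition means 1.
* **Mutation overlay**: a hotspot is a position with strictly more than 3
  somatic mutations.
* **Multiple testing**: BH within region.  q-values are reported alongside
  uncorrected P-values; QQ diagnostics (`qq_data()`) use uncorrected P.

## Known limitations

* The common-dispersion exact test has no per-position dispersion and no
  covariates; strong per-position variance heterogeneity would miscalibrate
  it.
* The window correction subtracts a baseline containing the site's own
  signal; for isolated sites this is a ~2% shrinkage of `log2 f`, but
  densely clustered strong sites shrink each other.
* Class normalization forces mean zero per class per region; a region where
  one class is genuinely, uniformly modulated would have that signal
  removed.
* The nearest-neighbor classifier is only as good as its exemplars; the
  shipped defaults are synthetic.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulation_config(region_length = 4000, depth = 100, seed = 1)
sim <- simulate_dataset(cfg, n_bound = c(ETS = 2, SRF = 1, NFY = 1),
                        n_unbound = c(ETS = 2, SRF = 1, NFY = 1),
                        min_gap = 100)
prof <- compare_groups(sim$tracks, "cellular", "naked")
sites <- classify_sites(prof, sim$sequence)
head(sites[sites$informative, c("start", "strand", "factor", "predicted")])
```
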