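---
title: "Meta-metabolome ecology: models, null models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-metabolome ecology: models, null models, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmeco)
```

## The problem

Ultrahigh-resolution mass spectrometry (FTICR-MS) resolves thousands of
individual molecular formulas in a single dissolved organic matter sample.
Treating each detected peak as a "taxon" and each sample as an ecological
assemblage lets us ask a question multivariate ordination cannot answer:
*which processes* — deterministic selection by the environment, or
stochastic dispersal and drift — structure the variation in metabolite
composition across space? `mmeco` implements this meta-metabolome ecology
workflow: it replaces the phylogeny required by classical community
phylogenetics with *relational dendrograms* built from the peaks themselves,
and then applies the standard null-model machinery (NRI, NTI, βNTI,
Raup–Crick) to binary peak-by-sample incidence data.

All analyses are presence/absence based. FTICR-MS peak intensities are not
comparable across samples because of charge competition during ionisation,
so a peak is either detected or below the limit of detection; any positive
reported intensity counts as present.

## The three relational dendrograms

A dendrogram supplies the between-peak distances (`d_ij`) that every
downstream metric consumes. Three constructions are supported; all are
clustered with UPGMA (average-linkage `hclust`), giving rooted ultrametric
trees.

**Molecular characteristics dendrogram (MCD).** Each formula-assigned peak
is a point in a trait space of elemental counts (C, H, N, O, S, P) plus
derived statistics: double-bond equivalents
`DBE = 1 + (2C − H + N + P)/2`, the modified aromaticity index
(Koch–Dittmar form)
`AImod = (1 + C − 0.5·O − S − 0.5·H)/(C − 0.5·O − N − S − P)`, and the
CH2-based Kendrick mass defect. The MCD clusters the plain Euclidean
distances between these vectors. Two design points deserve note:

* *No column scaling by default.* The distances are plain Euclidean over
  the raw property table, matching the default behaviour of the standard
  distance/clustering tools for this analysis. Because elemental counts and
  the Kendrick defect live on very different scales, `mcd_distance()`
  exposes `standardize = TRUE` for users who prefer z-scored traits.
* *Trait list.* The default columns are the elemental counts plus DBE,
  AImod and the Kendrick defect. The nominal oxidation state of carbon
  (NOSC, LaRowe–Van Cappellen, computed for the neutral molecule) and the
  derived Gibbs free energy of carbon oxidation
  (`ΔG° = 60.3 − 28.5·NOSC` kJ per mol C) are always computed and can be
  added through the `columns` argument; they are linear combinations of
  information already in the element counts, so they are not defaults.
  AImod is clamped into [0, 1]: negative raw values (highly saturated
  molecules) and values past 1 are artefacts of the index's denominator,
  not meaningful aromaticity.

**Transformation dendrogram (TD).** Every pairwise mass difference between
peaks is compared against a database of exact masses of biochemical
gains/losses (amino-acid residues, sugars, CH2, H2O, CO2, phosphate, ...).
A matched difference becomes an edge in a transformation network. The TD
uses the largest connected component of that network (peaks outside it are
discarded), takes the stepwise shortest-path distance — the minimum number
of transformations connecting two peaks — and divides the whole matrix by
its maximum so distances lie in [0, 1] with maximum exactly 1. Dividing by
the maximum (rather than min–max rescaling) is deliberate: hop counts start
at 1, and subtracting that minimum would make directly-connected peaks
indistinguishable from identical ones.

The matching tolerance defaults to *1 ppm of the transformation mass*, the
windows ultrahigh-resolution instruments justify. For light transformations
this is a very strict window (CH2 at 1 ppm is ±1.4e-5 Da) — stricter than
typical alignment precision — so an absolute-Da mode
(`tol_mode = "absolute"`) is also provided; released mass-difference
pipelines commonly use a fixed window. Both settings are recorded in the
pipeline's provenance output. When several database entries fall inside the
tolerance of one mass gap, the pair still forms a single network edge but
every matching entry annotates it, and each annotation counts toward the
per-peak transformation totals — the totals count *transformations*, not
edges.

**Transformation-weighted characteristics dendrogram (TWCD).** The MCD and
standardised TD matrices are combined by their entrywise (Hadamard) product
on the peaks they share. Because the TD factor lies in [0, 1], molecular
characteristic differences are *down-weighted* toward zero for peaks that
are few transformation steps apart; the TWCD entry never exceeds the MCD
entry. The entrywise reading of "matrix multiplication" is the only one
that preserves the symmetry and zero diagonal of a distance matrix and
produces this down-weighting, so it is the implemented meaning. The TD is
standardised on its full largest component first and only then restricted
to the formula-assigned intersection.

**Determinism.** Peak identity is the neutral mass printed to four decimals
(FTICR reporting precision); ids are sorted lexicographically before
clustering, so merge-order ties cannot make two runs differ.

## Diversity metrics

Per sample: richness (peak count), dendrogram diversity
(`DD = Σ L_b`, the Faith-type sum of branch lengths spanning the detected
peaks, root path included by default to match the convention of the
reference implementation), mean pairwise distance
(`MPD = Σ d_ij / (S(S−1))`) and mean nearest taxon distance
(`MNTD = (1/S) Σ d_i,min`), both abundance-unweighted. Samples with fewer
than two detected peaks report `NA` for MPD/MNTD.

Per sample pair: Jaccard dissimilarity on incidence, unweighted UniFrac
(branch length unique to either sample over branch length reached by
either), and βMNTD — the average, over the two directions, of each peak's
minimum distance to the other sample's peaks:

βMNTD = ½ [ (1/n_k) Σ min d(i_k, j_m) + (1/n_m) Σ min d(i_m, j_k) ].

This is the canonical two-direction mean with presence/absence weights
(f = 1/S). Note that one widely used reference routine pools the two
min-vectors into a single mean when run abundance-unweighted, which differs
from the equation above whenever the two samples have unequal richness; on
binary data its abundance-weighted mode reproduces the two-direction mean
exactly, and the package's tests cross-check against that mode.

## Null models and process inference

All null models randomise by **tip shuffling**: leaf labels are permuted
across the *whole* dendrogram (equivalently, the distance-matrix labels are
permuted), keeping topology and branch lengths fixed. Peaks present in the
incidence matrix but absent from a given dendrogram are dropped for that
dendrogram's analyses with a warning — the three dendrograms legitimately
cover different peak subsets.

* **NRI / NTI** (per sample): standardised effect sizes of MPD/MNTD against
  999 tip-shuffled nulls, multiplied by −1 so positive values mean
  clustering. A sample containing every leaf has zero null variance and is
  flagged degenerate rather than given an infinite score.
* **βNTI** (per pair): the standardised effect of βMNTD. The sign is
  `z = (obs − null mean)/null sd` *without* a −1 factor, so that z > +2
  means assemblages more divergent than chance (variable selection) and
  z < −2 more similar than chance (homogeneous selection) — the convention
  required by the standard interpretation of the index. A
  `sign_convention = "negated"` flag restores the flipped form for
  comparison with formulations that print an explicit −1.
* **Raup–Crick** (per pair): null assemblages are drawn from the regional
  pool (the union of detected peaks) at each sample's observed richness,
  without replacement, with probability proportional to occupancy frequency
  across samples (a `"uniform"` option exists). The observed Sørensen
  dissimilarity is located in the null distribution with ties counted at
  half weight (mid-P; required so that two identical samples spanning the
  whole pool land at RC = 0 rather than an arbitrary extreme), then rescaled
  to [−1, 1]. The default is 9999 draws per pair.
* **Classification**: z > 2 → variable selection; z < −2 → homogeneous
  selection; otherwise RC > 0.95 → dispersal limitation, RC < −0.95 →
  homogenizing dispersal, else undominated. Pairs with |z| < 2 but no RC
  value are labelled `undominated_unresolved` rather than silently merged.

`mme_assembly()` packages βNTI + Raup–Crick + classification into a single
fitted object with `print`, `summary`, `coef` and `plot` methods; summaries
are reported per group-pair block (e.g. pore-vs-surface) when sample groups
are known. By default all pairs are classified in one pass and summarised
by block; rebuilding pools per subset is possible by subsetting the
incidence matrix before fitting.

## The synthetic-data generator

`gen_formula_universe()` samples CHONSP formulas under realistic elemental
bounds (C 4–50, H ≤ 2C+2, O ≤ C+2, N ≤ 4, S ≤ 2, P ≤ 1, DBE ≥ 0, neutral
mass 200–900 Da). Half the formulas (by default) are created by adding a
biochemical transformation to an existing formula, which guarantees a
non-trivially connected transformation network — exactly the structure that
makes real DOM amenable to mass-difference analysis. `gen_assemblages()`
draws samples under four regimes:

* *neutral* — each sample draws its richness from shared lognormal(0, 1)
  occupancy weights (a plausible skewed occupancy distribution; the tested
  properties do not depend on its exact shape);
* *homogeneous selection* — all samples draw from one central NOSC window
  (30%–70% quantiles of the universe);
* *variable selection* — each habitat draws from its own disjoint NOSC
  tail (below the 40% / above the 60% quantile). NOSC is the trait filtered
  on because it is continuous, formula-derived, and maps onto the
  thermodynamic-favourability arguments used to motivate deterministic
  selection of metabolites;
* *mixing* — all samples are perturbed copies of one template (each present
  peak resampled with probability 0.05, richness preserved).

What the generator does *not* emulate: intensity structure beyond binary
presence, isotopologue patterns, ionisation efficiency, alignment error, or
a realistic (thousands-of-peaks) universe size. Passing the recovery tests
therefore demonstrates that the inference machinery identifies the
generating process when its assumptions hold — not that any particular
field dataset is stochastically or deterministically assembled.

## Validation design and problem sizes

The test suite validates every metric against independent brute-force
oracles (textbook UPGMA agglomeration, exhaustive triple-loop edge
matching, first-principles MPD/MNTD/βMNTD/branch-sum computations) on small
instances, and against established reference implementations where they
exist as cross-checks. Null-model behaviour is validated at the package's
chosen simulation size: 300-peak universes, two habitats of 10 samples,
richness 60, 999 null draws (Raup–Crick validation runs also use 999 draws
per pair; the function default remains 9999).

One calibration subtlety: under neutral assembly the per-run *mean* NRI/NTI
across the 20 samples is unbiased but dominated by the shared universe and
occupancy draw — the 20 per-sample indices are strongly correlated, so a
single run behaves like one effective observation with a spread of roughly
±0.4. The calibration tests therefore average over eight replicate neutral
universes, which measures the property (mean ≈ 0) rather than a single
draw. The βNTI significance fraction is much better behaved (190 weakly
correlated pairs) and is asserted on a single run.

## Known limitations

* The built-in transformation database is a reconstruction of the commonly
  used biochemical gain/loss lists (68 entries, exact masses computed from
  element counts). Transformation counts and network structure on real data
  will differ from analyses run with other databases; supply your own via
  `read_transformation_database()` for comparability.
* Whether a per-peak "transformation count" should be network degree or
  annotation-weighted degree is ambiguous in common usage; the package
  counts one per matched database entry (annotation-weighted). With the
  default 1 ppm tolerance the two rarely differ.
* TD distances exist only inside the largest network component; analyses on
  the TD/TWCD silently concern that subset (the pipeline logs per-dendrogram
  peak counts for exactly this reason).
* Raup–Crick pool definition is the loaded sample set; regional pools
  beyond it, abundance-weighted βNTI, and bin-level process partitioning
  are out of scope.
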