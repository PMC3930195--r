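---
title: "hydroscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hydroscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroscan)
```

## The problem

Hydrophobic residues (Val, Ile, Leu, Met, Phe) drive globular protein
folding and are predominantly buried, yet a substantial fraction ends up on
the solvent accessible surface. Knowing which hydrophobic residues of a
sequence are surface exposed — ideally without a structure — guides
stability engineering and the choice of modification sites. `hydroscan`
implements a complete two-route method: a structural route that measures
and classifies solvent accessibility, and a sequence route that predicts
the solvation state of hydrophobic residues from how well hydrophobicity is
conserved among homologs.

## Accessible surface area

The accessible surface is the locus of a probe sphere's centre rolled over
the protein's van der Waals surface. `lee_richards_asa()` computes it by
slicing: each atom's probe-inflated sphere (radius $R = r_{vdw} +
r_{probe}$) is cut into sections perpendicular to $z$ at spacing $\Delta Z$,
and each section contributes

$$\mathrm{ASA} = \sum_i \frac{R}{\sqrt{R^2 - Z_i^2}} \; L_i \, D,$$

where $Z_i$ is the section's offset from the sphere centre, $L_i$ the arc
length of the section circle not occluded by any neighbouring inflated
sphere, and $D$ the section's slab thickness. Occlusion on a section is
resolved exactly: every neighbour intersecting the section plane cuts an
angular interval out of the circle, and the accessible arc is the
complement of the interval union — the only discretisation is along $z$.

Numerical choices:

* Sections are placed at the midpoints of slabs obtained by cutting
  $[-R, R]$ every $\Delta Z$ (plus a final partial slab), with $D$ the slab
  width. Interior slabs have $D = \Delta Z$; the pole slab is shortened,
  which is the $\Delta'Z = \min(\Delta Z / 2,\, R - Z_i)$ edge rule. With
  this tiling an isolated sphere sums to exactly $4\pi R^2$ for any
  $\Delta Z$, and the residual error for occluded atoms comes only from arc
  lengths varying within a slab.
* Defaults follow standard accessibility practice: probe 1.4 Å,
  $\Delta Z = 0.05$ Å, element radii C 1.87, N 1.65, O 1.40, S 1.85 Å. All
  are arguments.
* Exactly coincident atoms with equal radii would occlude each other into
  mutual zero area; they are instead treated as duplicates — the first
  keeps its area, later ones score 0 and do not occlude. Non-finite
  coordinates are an error.

`shrake_rupley_asa()` is an independent brute-force check used by the test
suite: a deterministic Fibonacci lattice of points on each inflated sphere,
area $= 4\pi R^2$ times the fraction of points outside all neighbours. At
2000 points its quantum is about 0.07 Å² per point, so for slivers of a few
Å² the oracle's own sampling noise, not the slice method, limits agreement;
the tests therefore accept 2% relative *or* 0.5 Å² absolute agreement per
atom. At 20000 points the two methods agree to well under 1% even on
slivers.

## RSA and the two-state classification

Residue ASA (summed heavy atoms) is normalised by the residue type's area
in an extended Ala-X-Ala tripeptide to give RSA in percent. Two reference
conventions ship with the package (`reference_asa()`): the standard
Hubbard–Thornton tabulation for real structures, and a `single-sphere`
reference computed at call time from a three-pseudo-atom extended chain,
matching the fixture generator's one-sphere-per-residue convention so the
synthetic pipeline is self-consistent.

Classification uses a 7% RSA threshold. The two-state rule is stated as
"greater than 7 exposed, less than 7 buried", which leaves exactly 7
unassigned; `classify_state()` uses the half-open rule RSA ≥ 7 → exposed.
The exposed-residue count is non-increasing in the threshold (a tested
invariant).

## Propensities

For residue type $t$, the surface propensity is
$(n_{t,\mathrm{exp}} / n_{\mathrm{exp}}) / (n_t / n)$ and the buried
propensity its buried-population analogue; flanking propensities apply the
same normalisation to the residues found at offsets ±1 and ±2 from
hydrophobic anchors of a given state. Choices:

* The anchor set defaults to {V, I, L, M, F} and is an argument, because
  the broader "hydrophobic" sets used in composition statistics (including
  A, Y, W, sometimes C) are not consistently defined; results are reported
  per anchor set rather than guessing one.
* Anchors whose ±k neighbour falls outside the chain are skipped for that
  offset — no wrapping, no padding.
* ±k propensities are computed separately and also pooled, since the two
  directions are usually displayed jointly.

By construction the composition-weighted mean of every propensity column is
exactly 1; the tests verify this to 1e−9 and check flanking counts against
a brute-force pair enumeration.

## Hydrophobicity conservation score

Given a query-anchored alignment (homologs filtered at > 30% identity to
the query, identity = matches over mutually non-gap columns), each non-gap
query column is scored over the homolog rows:

| character | weight |
|---|---|
| V, I, L, M, F | 1 |
| A, Y, W | 0.5 |
| other residues | −2 |
| gap | −2, plus an extra penalty (default −2, total −4) |

The raw sum is normalised to $100 \cdot \mathrm{raw} / (n_{hom} \cdot 1)$ —
percent of the all-hydrophobic maximum — and binned into `<0`,
`0 to 10`, …, `90 to 100`. Design decisions, all exposed as arguments:

* **Gap extra penalty.** The scheme prescribes an unquantified extra
  penalty beyond the gap's −2; the default doubles it (total −4) so that a
  gap scores strictly worse than a polar residue, which is clearly the
  intent.
* **Cysteine** is unassigned by the conservation scheme (neither
  hydrophobic nor partial). It defaults to 0.5 by analogy with its full
  weight in the flanking scheme and its intermediate hydrophobicity.
* **Normalisation.** Percent-of-maximum is the one scale that caps at 100,
  admits the negative bin, and is independent of homolog count; the floor
  with default weights is −400.
* **The query row is excluded** from its own columns (self-counting would
  inflate conservation); `include_query = TRUE` restores it.
* **Bin boundaries** are lower-inclusive with the top bin closed — the
  printed bin labels overlap at multiples of 10, so one consistent
  half-open rule is applied.

## Confidence scores and prediction

From hydrophobic residues labelled by the structure route,
`build_bin_table()` tabulates per conservation bin the percentage relative
frequency of exposed and of buried residues (each column sums to 100). The
bin's exposed confidence is the ratio of the two frequencies, and the
buried confidence its reciprocal. The source material describes the
confidence as a ratio of per-state "normalized scores"; any common
normalisation of the two columns cancels in the ratio, and this reading
reproduces the published confidence table from its own frequency columns to
within 0.015 (most entries agree to printed truncation; a few low bins
differ by up to ~0.04 because the original ratios were evidently taken on
unrounded frequencies).

`predict_state()` calls a hydrophobic residue exposed when its bin's
exposed confidence is strictly above 2.07. The published account of the
threshold is internally inconsistent (2.07 is described as a buried
confidence in the 60–70 bin, where the confidence table shows 1.21; 2.07
appears in the frequency table instead). The only reading consistent with
the confidence table's ordering — low-conservation bins have exposed
confidence well above 2.07, high bins well below — is as an
exposed-confidence decision threshold, which is the default and is
configurable. Bins with zero frequency in one state get undefined
confidence and are excluded from prediction with a warning.

A bundled frequency table derived from a survey of 218 nonredundant
monomeric protein structures (`reference_bin_table()`) acts as the default
trained model for sequence-only use.

## Flanking refinement

`flanking_index()` averages hydrophobicity weights (F/I/L/M/V/C 1,
A/Y/W 0.75, S/T 0.35, others 0.15) over the up-to-four neighbours at
offsets ±1, ±2, truncated at termini, giving an index in [0.15, 1]. The
published method improves accuracy using this flanking knowledge but does
not state the combination rule, so `refine_predictions()` implements a
fully parameterised, conservative one: only calls whose bin confidence lies
within `margin` of the threshold can flip, an exposed call flips to buried
when the window is strongly hydrophobic (index ≥ 0.75), a buried call flips
to exposed when it is strongly hydrophilic (index ≤ 0.35), and every flip
is logged. In the pipeline the refinement is off by default (`refine =
FALSE`); the function's own default `margin = 1` applies when it is invoked
directly. With `margin = 0` refinement is a no-op.

Accuracy is evaluated as (tp + tn) / (tp + fp + fn + tn) with exposed as
the positive class.

## Synthetic fixtures: what they do and do not show

`gen_structure()` emits single-pseudo-atom "residues" (CB-like 1.87 Å
carbon spheres) — an analytic convention, not side-chain geometry. The
`two-shell` style seals each planned buried residue inside a 12-vertex
icosahedral cage of exposed residues at 3.3 Å: the occlusion cap of each
cage sphere (half-angle ≈ 59.7°) exceeds the icosahedron's covering radius
(≈ 37.4°), so the central sphere's accessibility is exactly zero by
construction and the truth labels are geometric, not computed by the code
under test. `gen_alignment()` composes homolog columns whose normalised
conservation score lands in a requested bin exactly under the default
weights, spreading mismatches across rows so homolog identities stay above
the requested floor.

The end-to-end benchmark draws true states at the reference class balance
(22.9% of hydrophobic residues exposed) and conservation bins from each
state's reference frequency column, realises them as actual alignment
columns, re-scores them from scratch and predicts at threshold 2.07. Its
accuracy (> 0.70 required by the test, ≈ 0.8 observed at the default sizes:
600 residues, 10 homologs) shows the pipeline's internal consistency — that
the scoring, binning, confidence and thresholding stages compose correctly
under the reference bin separation. It does **not** validate the method on
real proteins: real alignments have phylogenetic correlation, real
side-chain packing is not single-sphere, and dataset-level survey figures
(hydrophobic composition, buried fraction, per-residue propensity values)
require the full nonredundant structure set, which is out of scope here.

## Problem sizes and determinism

The test suite runs at desk scale by choice: ASA cross-validation on 50
seeded clusters of ≤ 10 atoms (slice 0.05 Å vs. 2000 oracle points),
exhaustive conservation monotonicity over all depth-≤ 3 columns of a
four-letter alphabet, and the 600-residue benchmark above. All generators
take explicit seeds, restore the caller's RNG state, and are
bit-reproducible given the seed; `run_pipeline()` echoes its effective
configuration into the output directory so a run can be reproduced from its
artifacts alone.

## Known limitations

* Pure-R slicing is comfortable at fixture scale and for single domains,
  but large complexes would warrant a compiled inner loop.
* No polar/apolar ASA split, no nucleic-acid support, no intermediate
  (three-state) exposure classes.
* The identity filter consumes an existing alignment; homolog search and
  alignment construction are upstream of this package.
* The flanking refinement rule is this package's own construction (the
  published weights with an invented, parameterised combination rule) and
  should be treated as exploratory.
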