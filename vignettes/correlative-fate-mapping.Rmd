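---
title: "Correlative live/fixed fate mapping of basal radial glia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative live/fixed fate mapping of basal radial glia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bRGmap)
```

# The problem

Basal radial glial (bRG) cells are the dominant neural progenitors of the
human outer subventricular zone (OSVZ). Mapping their division modes requires
knowing the fate of both daughters of a live-imaged division, which live
imaging alone cannot provide: fate markers (SOX2 for radial glia, EOMES for
intermediate progenitors, NEUN for neurons) are only visible after fixation
and immunostaining. The correlative strategy implemented here closes that
gap: tissue slices are live imaged, then fixed and stained, and the
live-imaging fields of view (FOVs) are transferred onto the fixed mosaics by
registering the slice outlines themselves. Candidate cells inside the
transferred FOVs can then be matched to the live recordings (the final
cell-by-cell matching is a manual step and is out of scope here; this
package automates everything up to and including FOV transfer, and the
downstream statistics once marker calls exist).

`bRGmap` provides four layers:

1. **Registration** — slice segmentation (`segmentSlices`), shape/area
   pairing (`pairSlices`), flip-aware similarity alignment
   (`estimateTransform`) and FOV transfer (`annotateFovs`).
2. **Classification** — the marker-to-fate map (`classifyFate`), the
   division-mode taxonomy (`classifyDivision`), and cohort statistics
   (`summarizeModes`, `inheritanceCrosstab`, `hes1Assignment`,
   `depthStats`, `classifyMst`).
3. **Lineage model** — a multitype branching model of bRG output
   (`marginals`, `recurrenceCounts`, `closedFormCounts`,
   `asymptoticRatio`, `simulateLineages`, `perturbFateProbabilities`,
   `invertMarginals`).
4. **Synthetic data and fixtures** — generators with known ground truth
   (`generateSliceSet`, `generateDivisionDataset`) and deterministic
   encodings of published cohort counts (`fixtureHes1Cohort`,
   `fixtureFetalInheritance`).

# Registration

## Segmentation

Slices are millimetre-scale objects on a nearly uniform background, so
segmentation is deliberately simple: automatic global thresholding by the
inter-class variance (Otsu) criterion, with polarity auto-detected by taking
the minority intensity class as foreground — brightfield mosaics have dark
slices on a bright background, fluorescence tile scans the reverse, and
nothing in the inputs declares which is which. Morphological closing
(disc radius 3 px) and hole filling clean the mask; objects below `minArea`
(default 0.5 mm², the scale of organoid slices) are discarded; objects
touching the mosaic border are kept, dropped or flagged per `borderPolicy`.

Outlines are traced at the 0.5 iso-level of each object mask rather than
through boundary pixel centres: the sub-pixel polygon's area then matches
the object's pixel count to well under 1%, which keeps the polygon area,
the reported physical area and the mask-based ground truth consistent.
Coordinates are pixels, origin top-left, x rightward, y downward; vertex
order is canonicalized to positive signed area in this convention.

## Shape descriptor

Pairing needs a descriptor invariant to everything the fixation process can
do to a slice except change its shape: translation, rotation, a small scale
change, and a possible horizontal flip. The descriptor is the seven Hu
moment invariants computed from *exact polygon moments* (Green's theorem,
no rasterization), log-compressed as `sign(h) * log10(1 + |h|/1e-6)`.
Components 1–6 are invariant under similarity transforms; component 7
changes sign under reflection and carries chirality.

The `1e-6` scale in the log acts as a noise floor and is a deliberate
numerical choice: for these blob-like outlines the order-3 invariants
(components 5–7) have magnitudes around `1e-9`, where realistic boundary
noise freely flips their sign. A raw logarithm would amplify such sign flips
into order-of-magnitude descriptor distances (and, in our noise studies,
occasional mispairings of similar slices); compressing sub-`1e-6` values
towards zero makes the descriptor lean on its stable low-order components
while still preserving exact chirality information for noise-free
comparisons.

## Pairing

The pairing cost between a live and a fixed contour is

$$ c = w_{area}\,\bigl|\log(A_{live}/A_{fixed})\bigr|
     + w_{shape}\,\lVert d_{live} - d_{fixed}\rVert , $$

evaluated under both chirality hypotheses (the sign of the fixed contour's
7th component flipped or not), keeping the lower cost; ties favour the
unflipped hypothesis. Both weights default to 1. The optimal one-to-one
assignment is solved exactly with an in-package Hungarian algorithm
(shortest augmenting paths, O(n³)); no installed R package provides
linear-sum assignment, and the solver is cross-checked against brute-force
permutation enumeration in the tests.

Pairs costing more than `maxCost` are dissolved into the unmatched lists.
The default `maxCost = 0.5` was set once from the package's synthetic noise
study (20 six-slice sets at default noise): matched pairs cost at most
~0.13 (mean 0.045, sd 0.021) while mismatched combinations start near 0.9,
so 0.5 separates the two populations with a comfortable margin on both
sides. We report the raw study numbers rather than a mean-plus-3-sd rule
because the matched-cost distribution is visibly heavy-tailed and the
literal 3-sd cut (0.11) would sit below an observed true-match cost.

## Alignment

Each matched pair is aligned by a similarity transform with an optional
horizontal flip. The composition order is fixed package-wide and documented
because nothing upstream prescribes one:

$$ p' = s\,R(\theta)\,M\,p + t, $$

with the mirror $M$ (reflection of x about the vertical axis) applied
first, then scale, rotation, translation. Only horizontal flips are
modelled — that is the one degree of freedom slice mounting can introduce —
so general reflections are excluded by construction.

Estimation is coarse-to-fine iterative closest point (ICP): contours are
resampled to 256 vertices by arc length; a coarse stage (64 vertices, 12
start angles spaced 30° around the principal-axis estimate, 10 iterations
each) is run for each chirality hypothesis, and the best start per
hypothesis is refined at full resolution (nearest-vertex correspondence,
least-squares similarity fit per iteration, scale clamped to
`[0.95, 1.05]`, cap 100 iterations, convergence when the residual RMS
changes by less than `1e-4` px). The hypothesis with the lower final
residual decides the flip. The multi-start coarse stage exists because a
principal-axis-only initialization is ambiguous by 180° and unreliable for
nearly symmetric outlines, where single-start ICP can converge to a local
minimum with the wrong flip. Non-convergence raises a condition object
carrying the best transform so far rather than returning it silently.

Scale deserves a note: live (4X brightfield) and fixed (40X tile scan)
mosaics have different native pixel sizes, so scale is nominally fixed by
the pixel-size metadata; the residual ±5% window only absorbs calibration
error, and alignment is performed per matched slice contour (not once per
whole mosaic), which lets each slice absorb its own small fixation
distortion.

## FOV transfer

A field of view is a rectangle in live-mosaic coordinates attached to a
slice; its four corners and centre are pushed through that slice's
transform, giving a quadrilateral ROI on the stained image, tagged with the
slice's alignment residual. FOVs on unmatched slices are reported
separately rather than silently dropped.

# Classification

## Marker map and taxonomy

Fates follow a strict precedence **NEUN > EOMES > SOX2**: NEUN marks
terminal neuronal fate; ranking EOMES above SOX2 implements the observed
retention of the mother marker SOX2 in freshly differentiating daughters
(a SOX2+/EOMES+ cell is an IP, not a radial glia). Cells negative for all
three are `unclassified`. A `"na"` (not assessed) call is treated as
negative but flagged, so cohorts lacking a stain remain analyzable without
pretending the marker was measured.

The unordered daughter-fate pair maps onto the taxonomy: two bRG daughters
= symmetric proliferative; bRG + differentiating = asymmetric self-renewing
(indirect via an IP, direct via a neuron); two differentiating = symmetric
self-consuming (indirect/direct likewise). An IP + neuron pair is labelled
`mixed_IP_neuron` with a warning — it has never been observed in bRG
cohorts, and the warning is the package surfacing data that contradict that
rule rather than hiding it. "Direct" is defined as *daughter set contains a
neuron and no IP*, so the asymmetric bRG + neuron division counts as
direct.

## Cohort statistics

`summarizeModes` reports three nested breakdowns (proliferative vs
neurogenic; asymmetric vs symmetric among neurogenic; direct vs indirect
among neurogenic), each summing to one, with raw counts alongside.
`depthStats` summarizes division depth (micrometres from the apical
surface, increasing basally) per group and compares two named groups with a
two-tailed unpaired Student's t-test with pooled variance — the
equal-variance form, matching the published analyses; Welch's form is
available via `varEqual = FALSE`. `classifyMst` classifies mitotic somal
translocation from the net displacement in the pre-division window (default
2 h, threshold 10 µm, both configurable; the boundary uses ≥, so a
displacement exactly at threshold is directional and anything strictly
smaller is stationary). The published account says only that MST happens
"shortly before" cytokinesis, so window and threshold are explicit
parameters rather than constants.

# The branching model

Types are A (bRG, the only dividing type), B (IP) and C (neuron). A
division of an A cell produces two daughters according to probabilities
$p_{AA}, p_{AB}, p_{AC}, p_{BB}, p_{CC}$ (the IP + neuron outcome carries no
probability, matching its absence from observed cohorts; the marginal
formulas would gain $+p_{BC}$ terms if it were admitted). Expected counts
obey

$$ A_x = A_{x-1}\,\bar p_A, \qquad
   B_x = B_{x-1} + A_{x-1}\,\bar p_B, \qquad
   C_x = C_{x-1} + A_{x-1}\,\bar p_C, $$

with marginal production rates $\bar p_A = 2p_{AA} + p_{AB} + p_{AC}$,
$\bar p_B = p_{AB} + 2p_{BB}$, $\bar p_C = p_{AC} + 2p_{CC}$, which always
sum to 2. The closed forms are $A_x = A_0\bar p_A^{\,x}$ and
$B_x = A_0 \bar p_B (\bar p_A^x - 1)/(\bar p_A - 1)$ (likewise $C_x$), with
the analytic limit $B_x = A_0\bar p_B x$ used within `1e-9` of
$\bar p_A = 1$. For $\bar p_A > 1$ the non-bRG to bRG ratio converges to
$(2 - \bar p_A)/(\bar p_A - 1)$.

**B cells are terminal in this model.** Biologically IPs divide once more;
the model deliberately counts produced IPs rather than their descendants,
exactly as the recurrences above are written. Counts after $x$ *divisions*
are reported; "five generations" in common usage corresponds to $x = 4$.

`simulateLineages` is the stochastic counterpart (every A cell draws an
outcome independently each generation); both the deterministic recurrence
and the simulator are provided because either could be meant by a
"simulation" of expected output, and they agree in mean by construction.
`perturbFateProbabilities` moves probability mass between outcomes, by
default *relatively* ("reduce by 20%" reads most naturally as 20% *of* the
rate), with an absolute mode for the other reading.
`invertMarginals` recovers $(\bar p_A, \bar p_B, \bar p_C)$ from observed
expected counts and reports $|\bar p_A + \bar p_B + \bar p_C - 2|$ as a
consistency diagnostic: exact model output gives ~0, and published rounded
outputs (e.g. 5.75 bRG / 1.21 IP / 2.69 neurons from one bRG cell after
four divisions) give a residual of about 0.001 — the printed triple is
internally consistent with the printed model.

A worked vector used throughout the documentation and tests,
$(0.6, 0.2, 0.1, 0.05, 0.05)$, has marginals $(1.5, 0.3, 0.2)$ and yields
$(A_4, B_4, C_4) = (5.0625, 2.4375, 1.625)$:

```{r model}
p <- fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
marginals(p)
closedFormCounts(marginals(p), A0 = 1, x = 4)
```

# Synthetic data: what it emulates, and what it does not

## Slice sets

`generateSliceSet` builds matched live/fixed mosaic pairs with full ground
truth. Slices are random smooth star-convex blobs — a base radius times
`1 + sum(a_k cos(k theta + phi_k))` for harmonics k = 2..5 — placed on
disjoint grid cells so non-overlap is guaranteed by construction (an
explicit error is raised if the requested count cannot fit). Each fixed
slice is its live counterpart under a uniformly random rotation, a random
translation, and a horizontal flip with probability 0.5 — flip chirality is
unknown a priori, so a fair coin is the natural phantom condition. Noise
has two dials: fractional area jitter (default 0.02) and boundary
deformation (two higher harmonics, default amplitude 1 px). At zero noise
the fixed mask is *exactly* the nearest-neighbour warp of the live mask
under the recorded transform, which gives the tests a pixel-for-pixel
oracle.

Two identifiability guarantees are part of the phantom design: harmonic
amplitudes are drawn from [0.03, 0.12] (never so round that orientation is
meaningless) and shapes are rejection-sampled until their mirror asymmetry
— the minimum over reflection axes of the RMS difference between the radius
profile and its reflection — is at least 3 px, comfortably above the
boundary-noise scale. Without the floor, occasional near-achiral blobs
appear whose recorded flip flag is physically undetectable by any method,
making "the" ground-truth flip meaningless for those slices.

What the phantom does **not** emulate: illumination gradients, staining
texture, out-of-focus blur, torn or folded slices, or non-rigid fixation
distortion (shrinkage beyond ±5% scale, local warps). Passing the
registration tests therefore demonstrates correctness of the geometry
pipeline, not robustness to every real-world artefact.

## Division cohorts

`generateDivisionDataset` draws division records from a `CohortProfile`:
outcome from the profile's probabilities; daughter markers from the
fate-to-marker map with differentiating daughters retaining SOX2 with
probability `markerRetentionProb` (default 0.5 — retention is described as
frequent but unquantified); depth from a normal law with per-outcome mean
and common sd, truncated at zero (only group means are reported in the
literature, so the spread is a parameter, default 150 µm); exactly one
process-inheriting daughter per division (the self-renewing one with
probability `inheritanceSelfrenewalProb` in asymmetric divisions, a coin
flip otherwise); HES1 detectable only ever in bRG daughters (with
probability `hes1DetectionProb`, reflecting its oscillatory expression);
and MST drawn as 25% stationary with the remainder split evenly between
apical and basal. The generating outcome is stored in `true_mode`, so
classification recovery is testable exactly.

Two built-in profiles exist. `profileGW17` encodes a gestational-week-17
fetal cohort: outcome probabilities (0.6, 0.1496, 0.1224, 0.0704, 0.0576)
chosen once to match the described fetal ranges (majority proliferative;
about a third of neurogenic divisions self-consuming; close to half
direct), indirect neurogenic divisions centred at 800 µm and direct ones at
1306 µm from the apical surface. `profileWeek8` is an illustrative
young-organoid profile using the worked vector above; stage-resolved
organoid probabilities are published only in figure form and are not
encoded here.

## Fixtures of published counts

Two deterministic fixtures encode printed cohort facts for regression
testing: `fixtureHes1Cohort` (276 organoid divisions: 186 symmetric
proliferative, 53 asymmetric, 37 symmetric self-consuming; 16 asymmetric
divisions with detectable HES1, always in the EOMES−/NEUN− daughter, 8 of
16 inheriting the basal process) and `fixtureFetalInheritance` (82 fetal
asymmetric divisions; 52.4% of process-inheriting daughters remain bRG,
converted to integer counts 43/39 by round-half-up, recorded in the fixture
metadata). Where the published account fixes only totals, the remaining
construction choices (e.g. the 27/26 indirect/direct split among the 53
asymmetric divisions) are arbitrary and recorded in each fixture's
`"metadata"` attribute. No fixture encodes the 79-division organoid
inheritance cohort: it is described only as "half" of an odd-sized cohort,
so exact counts cannot be reconstructed.

# Reproducibility and problem sizes

Every generator is a pure function of its parameters and a single integer
seed, drawn through R's RNG with the caller's RNG state saved and restored.
The validation suite runs registration recovery on 20 generated slice sets
(6 slices each, 512 px mosaics, default noise), model equivalence on 1,000
random probability vectors with up to 20 divisions, a 10,000-replicate
stochastic simulation against the closed form, and cohort recovery at
1,000–10,000 records — sizes at which binomial/normal 3-standard-error
bands are tight enough to detect real defects while the whole suite stays
fast.

# Known limitations

- Registration assumes slices stay rigid up to similarity + flip; strong
  non-rigid fixation distortion would inflate residuals and is not
  modelled.
- The Hungarian pairing is globally optimal for the given costs, but the
  costs themselves use only area and moment invariants; two genuinely
  near-identical slices can in principle swap (raising `w_shape`, or
  checking the reported costs, mitigates).
- `classifyFate` trusts upstream ternary marker calls; no intensity
  thresholding is performed, and gliogenic fates are outside the taxonomy.
- The branching model treats IPs as terminal and has no cell-cycle time,
  death, or age structure; it predicts composition after a number of
  divisions, not a timeline.
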