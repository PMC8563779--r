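---
title: "Outline morphometrics with shape-changing chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics with shape-changing chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainmorph)
```

## The model

`chainmorph` compares families of outline curves — 2D or 3D, open or closed,
smooth or serrated — by fitting a single *shape-changing chain* to all of
them. Each outline ("design profile") is first resampled into a *target
profile*: a piecewise-linear curve whose consecutive points all lie one
common chord length apart. That chord, the *piece*, is the unit in which
every length in the analysis is expressed, so arc length differences between
specimens become integer piece counts.

The chain is an ordered sequence of typed segments, each matched to one
portion of every profile:

* **M-segment** — rigid: a fixed polyline, the rigid-motion-only Procrustes
  mean of its portions, which must contain the same number of pieces on
  every profile. It models regions with little variation and contributes no
  free shape parameters.
* **C-segment** — a planar circular arc of fitted constant curvature and
  variable length (piece count); the 2D special case of the H-segment.
* **H-segment** — a circular helix of fitted constant curvature and torsion,
  variable length; suited to smooth 3D regions.
* **G-segment** — scalable: a fixed shape stored as a unit-arc-length
  template, rescaled per profile; it models growth, regions that keep their
  shape while changing size.

A study is described by a segment type vector (e.g. `M G M` or
`M G H | H G M` with `|` separating sub-profiles) and a *segment matrix*
`m[j, e]`: the pieces given to segment `e` on profile `j`. Row sums equal
each profile's piece count, and M columns are constant across rows.
Boundary point indices are the cumulative sums of each row. Every generated
segment is rigidly aligned (rotation with determinant +1 and translation —
no scaling, no reflection, since biological outlines have handedness) to its
portion by least squares; the *error matrix* stores the maximum pointwise
distance per segment and profile. Four summaries are used: the matrix
maximum and mean, per-profile row means, and a per-profile mean pointwise
error normalized by the profile's point count (the quantity both optimizers
monitor).

## Homologous segmentation

Portions are only comparable across specimens if their boundaries are
homologous. Primary boundaries come from anatomy or from the
*relative-angle* method: the turning angle at point `i` measured between
chords spanning `k` points. At `k = 1` this is the exterior angle between
neighbouring pieces; widening `k` low-pass filters the outline, so
high-frequency serrations ("burrs") lose their angle while global corners
("apices") keep it. `apex_count_sweep()` shows the detected-apex count
stabilizing once `k` exceeds the burr wavelength; the plateau count is the
number of global apices. Points at or above the threshold `T` are grouped
into contiguous runs (merged across the seam of closed outlines) and each
run contributes its angle maximum, with ties broken toward the lower index.
`k` and `T` are user choices per group of shapes, in points and degrees;
the sweep supports the choice but does not automate it. When noise produces
an extra spurious apex on individual specimens, `select_apices()` keeps the
strongest ones so all profiles carry the same number of primary points.

Supplementary boundaries subdivide the sub-profiles between primary points
until the profile has the requested `q` portions. A genetic algorithm over
integer boundary positions (population 50, 100 generations, one-point
crossover 0.8, per-gene mutation 0.05, elitism 1, seeded) minimizes the
squared deviation of portion sizes from the even share `(N - 1)/q`. The
initial population contains an even-spacing heuristic, so the result never
does worse than it; on small instances it equals exhaustive search, and
without primary constraints it attains the analytic optimum of the integer
partition. A GA is deliberate here: with primary points fixed the objective
is separable and almost trivial, but the same machinery accepts arbitrary
constraint patterns.

For closed outlines the cyclic start is relocated to the first detected
apex (`rotate_closed_profile()`), so portions begin at homologous positions;
where the start would otherwise be is arbitrary digitization order.

## Optimization of segment lengths

Two error-driven refinements operate on the segment matrix, never moving
primary boundaries, always conserving row sums and M columns:

* `optimize_piecewise()` — per profile, one piece moves from the
  worst-matched resizable segment to the best-matched resizable segment in
  the same sub-profile; the chain is rebuilt and the move kept only if that
  profile's normalized error decreases. Greedy acceptance makes the error
  sequence non-increasing by construction. One-piece steps are a choice:
  they are slow but cannot overshoot.
* `optimize_worst_profiles()` — ranks profiles by normalized error and
  re-randomizes the resizable lengths of the worst share (default 10%).
  Proposals are scored against the *current* segment models — the matching
  scheme of the other profiles stays untouched while candidates are
  compared — and the winning proposal is confirmed by a full rebuild.
  Scoring proposals by full refits was tried and rejected: the consensus
  templates then absorb the perturbation, masking improvements, at roughly
  thirty times the cost.

Both optimizers are local. If *every* profile is mis-segmented the same way
(say, all cut at the arc midpoint when the true joint sits at 30% of the
arc), the mis-segmentation is self-consistent — each template simply learns
the corner — and no per-profile move can escape it. Homologous primary
points from apex detection are what anchors the fit near the truth;
the optimizers refine within that basin.

## Numerical choices

* **Resampling.** The common chord for a profile is solved so that exactly
  `round(arc length / piece length)` chord steps land on the final vertex;
  all pieces are then *exactly* equal and endpoints exact. The traversed-arc
  function jumps at vertex-aligned roots on closed polylines (corner-cutting
  drift compounds through successive corners), so the solver brackets
  feasibility: walk failure and arc overshoot are both treated as the
  infeasible side, and the returned step is always walkable. Resampling an
  already-resampled profile at its achieved piece length reproduces it to
  well below `1e-9` pieces.
* **Curvature and torsion.** C-segments use the Taubin algebraic circle fit,
  whose line limit cleanly yields curvature 0; H-segments use the
  circumradius of consecutive point triples and the signed dihedral angle
  between consecutive osculating planes divided by the middle chord.
  Both converge to the true helix parameters at second order in the piece
  length; per-portion estimates are averaged, then averaged across portions
  without arc-length weighting.
* **Segment generation.** Arcs and helices are sampled at exact chord steps
  (the helix step solved by bisection to `1e-10`); G templates are rescaled
  and chord-resampled. Pieces of generated polylines match the nominal piece
  length to well under 1% at realistic discretizations; very coarse, highly
  curved G segments (say 5 pieces spanning a quarter circle) can deviate
  further because a chord is inherently shorter than its arc.
* **Procrustes.** Generalized Procrustes iterates to a mean-shape change
  below `1e-9`, rejecting reflections, and the converged pose is
  canonicalized to the mean shape's principal axes so results do not depend
  on the inputs' common orientation. Degenerate (coincident-point)
  configurations are an error.

## Statistics

Features from a fitted chain: signed orientation differences between
neighbouring segments (degrees, wrapped to `[-180, 180)`; the planar
direction-angle difference is inherently signed, with an absolute-value
option), piece-count length ratios of resizable segments (each column
scaled by its maximum, so values lie in `(0, 1]`), unit direction vectors
of segments in 3D, and optional arc length, apex count, burr count (an apex
count at a small interval and threshold), and anchor-point coordinates.

`stepwise_da()` performs forward-with-removal selection on the Wilks'
lambda partial F (defaults `f_enter = 3.84`, `f_remove = 2.71`, the classic
SPSS values; ties go to the smaller column index) and classifies with
linear DA on pooled covariance and equal priors, `g - 1` canonical
components for `g` groups. If nothing passes the entry threshold the result
is an explicit empty model, not an error. Note that at `f_enter = 3.84` a
pure-noise variable among nine has roughly a one-in-three chance of entering
alongside a truly informative one — that is the nature of stepwise F tests,
not a defect — so checks that demand *exactly* the informative variable use
a stricter threshold (10), which a strongly separated variable exceeds by
orders of magnitude. Leave-one-out cross-validation refits the classifier
on every n−1 subset with the variable set held fixed (selection is not
re-run per fold), skipping folds that would leave a group with fewer than
two training samples.

## What the synthetic generators emulate

* `generate_chain_profiles()` builds 2D open profiles from a known chain:
  fixed M template, fixed G template, per-profile resizable piece counts
  drawn around group means, inter-segment angles around group means, and
  isotropic Gaussian coordinate noise (default 0.05 pieces — the simplest
  noise model; digitization error is roughly isotropic at outline scale).
  Default joint angles are large enough (tens of degrees) that boundaries
  are detectable corners, as in real material where segment boundaries sit
  at anatomical features.
* `generate_leaflike()` makes closed serrated outlines: a radial base with
  exponentiated lobes plus a high-frequency burr sinusoid. Tips are
  sharpened (exponent 4) because with plain cosine lobes the inter-lobe
  valleys turn more sharply than the tips; real serrated leaves have pointed
  lobe tips. The generator returns the true tip angles.
* `generate_suturelike()` makes smooth open 3D arcs with group-specific
  rotation, translation, and length scaling plus small shape noise, and
  labels the endpoints as anchor landmarks.

These generators produce idealized data: no outline-tracing artifacts, no
missing regions, isotropic noise, groups that differ in exactly the stated
parameters. Tests passing on them show the machinery recovers known
structure under controlled conditions; they do not show that any particular
empirical dataset will classify well, and real studies still owe the usual
care in choosing segment types, `k`, `T`, and the portion count.

Problem sizes used throughout the tests and the reproduction script — 16 to
30 profiles of 60 to 600 pieces, chains of 2 to 4 segments — were chosen as
the smallest sets on which recovery rates and cross-validation are stable
across seeds.

## Known limitations

* Segment models are refitted from scratch at every optimizer evaluation;
  studies with hundreds of long profiles will feel it.
* C/H fitting assumes portions that are genuinely near-constant in curvature
  and torsion; across a sharp corner the averaged parameters are
  meaningless (use segmentation to keep corners at boundaries).
* The optimizers are greedy and local by design; there is no global search
  over segment matrices, and none is attempted.
* Burr counting is a raw apex count at user-stated small `k`, `T`; no
  further burr model is implied.

## A minimal run

```{r example, eval = FALSE}
gen <- generate_chain_profiles(p = 12, types = c("M", "G", "M"),
                               joint_mean = rbind(c(40, -35), c(60, -35)),
                               groups = c("a", "b"), noise_sd = 0.05,
                               seed = 1)
targets <- lapply(gen$profiles, resample_to_target, piece_length = 1)
segs <- lapply(targets, function(tp)
  place_supplementary_points(tp, detect_apices(tp, k = 3, T = 15), q = 3,
                             seed = 1))
sm <- build_segment_matrix(segs, c("M", "G", "M"))
chain <- build_chain(targets, segment_matrix = sm)
chain <- optimize_worst_profiles(chain, seed = 1)
feats <- assemble_features(chain, blocks = c("sigma", "lengths"))
stepwise_da(feats)
```
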