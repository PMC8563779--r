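# chainmorph

Outline-based geometric morphometrics with shape-changing kinematic chains.

`chainmorph` compares families of outline curves — 2D or 3D, open or closed,
smooth or heavily serrated — by fitting one *shape-changing chain* to all of
them and analyzing the chain's parameters instead of raw coordinates. It is
aimed at morphometric studies (bone profiles, leaf contours, cranial suture
curves) where landmark sets are sparse or arguable and Fourier-type outline
descriptors are hard to interpret.

## The method

Each outline is resampled into a *target profile* of `N` points whose
consecutive distances all equal one common *piece length*, so specimen size
differences become integer piece counts. A chain of typed segments is then
fitted across all `p` profiles at once:

| type | shape | size | models |
|------|-------|------|--------|
| M | fixed (rigid Procrustes mean) | fixed | conserved regions |
| C | circular arc, fitted curvature κ | variable | smooth 2D growth/rotation |
| H | circular helix, fitted κ and torsion τ | variable | smooth 3D regions |
| G | fixed template (unit arc length) | variable | isomorphic growth |

A `p × q` **segment matrix** `m[j, e]` assigns pieces to each segment on each
profile (row sums = piece counts, M columns constant); segmentation points
are its cumulative sums. Each generated segment is rigidly aligned to its
portion and the **error matrix** records the maximum point-to-point distance
`E[j, e]`, summarized by its maximum, mean, row means, and a per-profile
normalized mean pointwise error.

Homologous boundaries come from the *relative-angle* method — the turning
angle over a `k`-point interval, thresholded at `T` degrees, which filters
high-frequency serration ("burrs") from global corners ("apices") — plus a
seeded genetic algorithm that spreads supplementary boundaries evenly within
sub-profiles. Two error-driven optimizers refine segment lengths: a
piece-by-piece transfer pass and a re-randomization of the worst-matched
profiles. Chain parameters (inter-segment orientation differences σ, length
ratios g, 3D direction vectors u, apex/burr counts, arc length, anchor
coordinates) feed a stepwise linear discriminant analysis (Wilks'-lambda
partial-F selection, pooled covariance, equal priors) with leave-one-out
cross-validation.

## Worked example

Twelve synthetic open profiles from a known `[M G M]` chain, two groups
differing by 20° in the first joint angle, coordinate noise 0.05 pieces:

```r
library(chainmorph)

gen <- generate_chain_profiles(p = 12, types = c("M", "G", "M"),
                               joint_mean = rbind(c(40, -35), c(60, -35)),
                               groups = c("a", "b"), noise_sd = 0.05, seed = 1)
targets <- lapply(gen$profiles, resample_to_target, piece_length = 1)
segs <- lapply(targets, function(tp)
  place_supplementary_points(tp, detect_apices(tp, k = 3, T = 15), q = 3,
                             seed = 1))
sm <- build_segment_matrix(segs, c("M", "G", "M"))
chain <- optimize_worst_profiles(build_chain(targets, segment_matrix = sm),
                                 seed = 1)
chain
#> chain_fit: 12 profiles, 3 segments [M G M], 2D
#>   E_max 0.1871, E_mean 0.1008

feats <- assemble_features(chain, blocks = c("sigma", "lengths"))
head(feats, 3)
#>         id group sigma_1 sigma_2    g_2
#> 1 chain_01     a   39.48  -34.88 0.7966
#> 2 chain_02     b   59.60  -34.35 1.0000
#> 3 chain_03     a   38.81  -36.43 0.8644

stepwise_da(feats)
#> chain_da: 2 variables [sigma_1, g_2]
#>   accuracy 100.0%, LOOCV 100.0%
```

The fit reproduces the generator: matching error stays near a tenth of a
piece (`E_mean 0.10`), the orientation difference `sigma_1` recovers the
per-group joint angles (group means 39.5° and 59.1° against the true 40° and
60°), `g_2` is each specimen's G-segment length relative to the longest, and
the discriminant analysis separates the groups perfectly under
leave-one-out cross-validation.

The same functions drive 2D serrated closed outlines
(`generate_leaflike()`, `apex_count_sweep()` to pick the burr-filtering
interval) and 3D open curves with anchor landmarks (`generate_suturelike()`,
`segment_direction_3d()`); a YAML-configured pipeline
(`run_simulate()`/`run_fit()`/`run_features()`/`run_da()`, or
`inst/cli/chainmorph.R` from a shell) writes all artifacts to disk.

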