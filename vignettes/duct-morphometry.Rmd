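---
title: "Quantifying paired duct and vessel trees from resin-cast microCT masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paired duct and vessel trees from resin-cast microCT masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductr)
```

## The measurement problem

Double resin casting fills two lumenized systems of one organ — here
written as BD (bile duct) and PV (portal vein), though airway/artery pairs
work identically — with radiopaque resin, images them by micro-CT at
isotropic 6.5–12 µm resolution, and segments each system into a binary
mask. `ductr` turns such a pair of co-registered masks into numbers: how
large each tree is, how it branches, how its branches shorten and narrow
toward the periphery, how convoluted its ducts are, and how closely one
system tracks the other.

All spatial reasoning uses one convention: voxel indices are 1-based and a
voxel's physical position is its centre, `(index − 0.5) × voxel_size`.
Only isotropic grids are accepted; an anisotropic header is a hard error
rather than a silent resample, because every downstream distance would
otherwise be wrong by an axis-dependent factor.

## From mask to graph

**Skeletonization** (`skeletonize_mask`) is homotopic thinning: border
voxels are peeled in six directional subiterations (up, down, north,
south, east, west) per pass, and a voxel may only be deleted while it is a
*simple point* — its removal changes neither the number of 26-connected
foreground components nor the number of 6-connected background components
within its 3×3×3 neighbourhood. Candidates are collected per subiteration
and re-checked at deletion, so every single deletion is homotopic; curve
endpoints (exactly one 26-neighbour) are never deleted. The fixed point is
a one-voxel-wide curve skeleton with the same components and loops as the
mask: a solid cylinder reduces to a single straight voxel line, a torus
keeps exactly one cycle.

**Graph conversion** (`graph_from_skeleton`) classifies skeleton voxels by
degree (1 endpoint, 2 chain, ≥3 junction), clusters mutually adjacent
junction voxels into one node at the cluster centroid (deterministic and
orientation-independent), and walks chains of degree-2 voxels into links.
Every skeleton voxel is accounted for exactly once — in one node cluster
or one chain — which the tests assert as a conservation law. Isolated
cycles (anastomoses such as bridging ducts) get one artificial degree-2
*anchor* node so the cycle is representable as a self-link; this
convention is ours, chosen because it keeps the link set a faithful
partition of the skeleton.

Thinning can leave one- or two-voxel terminal spurs where a bump of the
digitized surface transiently became a locked endpoint. `prune_spurs`
removes endpoint links shorter than a threshold and splices the degree-2
junctions left behind. It is **off by default** — short real side branches
must not silently disappear — and used in the validation suite at 0.05 mm
(about four voxels, an order of magnitude below any real terminal branch
in the phantoms).

## The morphometric panel

| quantity | definition | default parameters |
|---|---|---|
| volume | foreground voxels × voxel volume | — |
| curved length | Σ of distances between neighbouring chain points | — |
| chord length | Σ of straight node-to-node link lengths | — |
| tortuosity | curved/chord × 100% − 100% | 0% = straight |
| main branch | origin-to-endpoint path of maximal curved length | origin required |
| junction merging | transitive union of branch points | 0.2 mm radius |
| side branch | child with chord dot product p over threshold inherits generation | p > 0.95 |
| diameter profile | 2 × min distance to eroded-mask boundary | every 1.5 mm, 5-sample smoothing |
| regions R1–R3 | equal thirds of Σ per-generation mean lengths | PV-derived S reused for BD |
| gap distance | non-resin span on the line between nearest skeleton points | curves 0.015–1.5 mm |
| branch-point distance | Euclidean distance to nearest other-system junction | curves 0.015–3 mm |

The 0.2 mm merge radius, the p > 0.95 collinearity rule, the 1.5 mm
diameter step with five-point smoothing, and the cumulative-curve ranges
are the established values for adult mouse liver at this resolution; all
are exposed in `pipeline_config()` and recorded in the output log, never
hard-coded. Two diameter region-window presets exist
(`region_windows_preset()`): 0–3 / 4.5–9 / 10.5–13.5 mm, and a narrower
0–1.5 / 3–6 / 7.5–9 mm variant for smaller lobes.

Some choices the definitions leave open, and how they are resolved here:

- *Diameter smoothing neighbours* are the adjacent 1.5 mm **samples**, not
  adjacent chain voxels (a flag-free choice: sample-level smoothing is
  what stabilizes a profile against single-voxel radius jitter); at the
  profile ends the window shrinks symmetrically down to one point.
- *Arc-length sampling* interpolates linearly between chain points so that
  samples sit at exact multiples of the step.
- *Region borders* close each region at the generation whose inclusion
  brings the cumulative `l_Gn` sum nearest to `k·S` (k = 1, 2), ties to
  the earlier generation, each region forced nonempty; an exhaustive
  search over all border pairs is kept in the tests as the oracle, and the
  greedy rule matches it on random length vectors.
- *Generations in cycles*: a link closing a cycle takes the minimum
  generation over its two approach paths (logged); when several children
  exceed the side-branch threshold only the most collinear one continues
  the parent's generation, preventing duplicate continuations.
- *Which generation gets the origin* is the user's call: the origin is a
  required input (mirroring manual hilar definition), snapped to the
  nearest node and rejected if it is farther than 20 voxels from any node
  (a likely wrong-system coordinate).

## Quantization: what voxel grids can and cannot support

Three systematic effects of measuring on a lattice are documented rather
than hidden, because they bound every accuracy statement in the tests:

**Digital chain length.** The curved length of a link is the cumulative
distance between neighbouring voxel centres. A 26-connected digital curve
overestimates the length of an oblique smooth curve by a
direction-dependent factor of up to ~8% (for a 2D direction at 22.5° the
chain alternates axis and diagonal steps: length
`sin θ·√2 + (cos θ − sin θ)` ≈ 1.083 per unit), averaging ~5.5% over
in-plane directions. Consequently a rasterized semicircular tube measures
~65% tortuosity against the analytic 57.08%, a straight-branched tree
shows a few percent residual "tortuosity", and rigid rotation of the same
tube moves the measurement by a few percent (the suite asserts 5%
rotation stability on a helical tube). Sub-voxel centreline refinement
would remove this bias but is deliberately out of scope: link chains stay
raw voxel centres, and axis-aligned straight tubes therefore measure
*exactly* 0% tortuosity, which anchors the scale. Cross-genotype
comparisons are unaffected to first order because the bias is common to
both groups; absolute tortuosities carry it.

**Boundary quantization.** The local radius is the minimal distance from
a skeleton point to the mask boundary (mask minus its erosion by the
one-voxel spherical element). Boundary voxel *centres* sit about half a
voxel inside the physical surface, so the raw minimum under-reports radii
by ~0.5–1 voxel; `radius_at` adds the half-voxel surface offset back
(`boundary_offset_vox = 0.5`, settable to 0 for the raw value). With the
offset, cylinder diameters are recovered within one voxel.

**Gap span.** The surface gap is measured as the distance between the
first and last non-resin voxel centres on the digital line (an
Amanatides–Woo traversal that visits every voxel the continuous segment
crosses — no diagonal leaks). Centre-to-centre measurement loses up to
half a voxel of gap at each surface, worst when a surface aligns exactly
with voxel centres; programmed gaps of 0–0.5 mm are recovered with mean
absolute error below two voxels. A `method = "radius"` variant
(skeleton-to-skeleton distance minus the two local radii) is provided for
comparison; the two agree for locally circular cross-sections but the
line-span definition is the default because it makes no cross-section
assumption.

## The phantom generator

`make_tree`/`make_dual_phantom` produce the ground truth every recovery
test runs against: binary-splitting trees with per-generation branch
lengths (default 1.2/0.85/0.6/0.45 mm — shortening peripherally as real
portal trees do), ±35° bifurcations about seeded random axes, root radius
0.05 mm tapering by 0.8 per generation, optional sinusoidal centreline
displacement, rasterized at 0.012 mm voxels by a voxel-centre-in-capsule
test (no antialiasing, matching binary-mask semantics). Dual phantoms are
planar trees with a companion offset perpendicular to the tree plane so
the programmed surface gap (uniform or ramped) is exact, and companion
radii one third of the primary's — the wild-type BD:PV calibre
stereotype. Self-intersecting geometries are re-drawn with a jittered
seed (up to ten attempts). Identical spec and seed give bit-identical
grids.

What the phantoms deliberately do **not** emulate: scanner physics (noise,
beam hardening), resin artefacts (bubbles, leakage, incomplete filling),
anastomoses/loops, non-binary splits, diameter irregularity along a
branch, and the manual segmentation step. Passing recovery tests
therefore demonstrate the *measurement* pipeline is correct on clean
geometry; they do not certify segmentation quality on real scans, and
masks with artefacts should be screened with `validate_mask` (component
census, sub-cut-off terminal twig flags — the four-voxel minimal
cross-section mirrors the smallest-canal segmentation cut-off; flagged,
never deleted, because enforcement belongs to segmentation, not
measurement).

## Degenerate inputs

Empty masks refuse to skeletonize but validate to a zero-component
report. Trees with fewer than three generations cannot form three
regions; the pipeline falls back to assigning each generation by where it
starts relative to S and 2S, with a warning. A second system whose total
is smaller than the reference region size goes entirely to R1 (warned); a
closure that would leave R3 empty forces the last generation into R3
(warned). A main branch shorter than the diameter step yields a single
sample at 0 with a warning. Unbranched systems skip the branch-point
analysis (there are no branch points); gap analysis still runs.
Cumulative curves append one overflow edge beyond their nominal range so
they always terminate at 100%.

## Validation scale

The test-suite phantoms are sized for routine re-running: single tubes of
60–600 voxels length, semicircle and helix tubes on grids of ~256 voxel
extent, twenty 4-generation trees (~250³ voxel grids, ~19 000 foreground
voxels each) for exact topology recovery, dual phantoms of 2–3
generations for gap recovery, and 100-vector sweeps for the region-border
oracle. The full suite completes in well under a minute on one core;
real lobe masks (hundreds of millions of voxels) run through the same
code paths, with thinning linear in foreground voxels times tube radius.

## Known limitations

- Absolute curved lengths and tortuosities inherit the digital
  chain-length bias discussed above; they are comparable across samples
  scanned and processed identically, not against analytic geometry beyond
  ~5–8%.
- Junction centroids displace slightly into the thicker parent branch for
  very asymmetric bifurcations; chord vectors (and hence side-branch
  classification) are robust to this at the default p threshold, but
  angles below ~15° between sibling branches will merge or misclassify.
- The radius estimate is the minimal distance to the boundary, i.e. the
  inscribed-sphere radius: for elliptical lumens it reports the minor
  semi-axis; cross-sectional shape analysis is out of scope.
- Cycles are measured and logged but generation numbers inside them
  depend on the breadth-first arrival order where the two approach paths
  tie.
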