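# ductr

Morphometric quantification of **paired tubular networks** from resin-cast
micro-CT binary masks — built for double resin casting experiments in which
two lumenized systems of one organ (the intrahepatic **bile duct (BD)** and
**portal vein (PV)** trees of a liver lobe, or airway and pulmonary artery
in lung) are injected with radiopaque resin, scanned, segmented, and
analyzed as co-registered 3D binary masks.

It is aimed at labs doing quantitative duct/vessel phenotyping — e.g.
comparing cholestatic mouse models against wild type — who need the full
morphometric panel from a pair of masks rather than manual measurements on
sections.

## What it computes

Each binary mask (isotropic voxels, typically 6.5–12 µm) is reduced to a
one-voxel-wide medial-axis skeleton by homotopic thinning (simple-point
deletion under 26/6 connectivity, endpoint-preserving), converted to a
network graph of nodes (endpoints, junctions) and links (skeleton point
chains), and measured:

- **Volume** `V = N_voxels · v³` and the BD:PV volume ratio.
- **Curved length** `L_c = Σᵢ‖pᵢ₊₁ − pᵢ‖` over link chains, **chord
  length** `L_ch` over straight node-to-node segments, and **tortuosity**
  `τ = (L_c / L_ch) · 100% − 100%` (0% = perfectly straight), for the whole
  system, the main (longest) branch, and per region.
- **Branch generations**: breadth-first from a manually defined (hilar)
  origin (generation 1); a child branch whose unit chord vector has dot
  product `p > 0.95` with its parent is a near-collinear continuation and
  inherits the parent's generation (side branching).
- **Furcation census** after merging branching points closer than 0.2 mm:
  bifurcations (2 outputs), trifurcations (3), higher-order (>3).
- **Regions R1/R2/R3** (hilar / intermediate / peripheral): generations are
  grouped so that the summed per-generation average branch lengths `l_Gn`
  make three equal regions of size `S = Σ l_Gn / 3`; the PV-derived `S` is
  reused to partition the BD tree. Per region: size, mean branch length,
  branch-count percentage, tortuosity.
- **Main-branch diameter profile**: local radius = minimal distance from
  the skeleton to the eroded-mask boundary, sampled every 1.5 mm and
  smoothed over five neighbouring samples; BD/PV diameter ratio per region
  window.
- **Dual-system proximity**: for every BD branch point, the 3D Euclidean
  distance to the nearest PV branch point; for every BD skeleton point, the
  surface **gap** `d_gap` measured as the non-resin span on the digital
  line to the nearest PV skeleton point; cumulative distribution curves
  (bins of 0.015 mm up to 1.5 mm for gaps, 3 mm for branch points) and the
  per-sample maximum gap.

A fully ground-truthed **phantom generator** (binary-splitting trees with
per-generation lengths, tapering radii, optional sinusoidal tortuosity, and
a companion tree at a programmed surface gap) backs every recovery test.

Masks are read/written as multipage TIFF, NRRD, or NIfTI-1; graphs export
to CSV and GraphML; reports to JSON/CSV.

## Worked example

A dual phantom stands in for a segmented scan pair (a real analysis starts
from `read_volume("bd.tif", voxel_size_mm = 0.012)` instead):

```r
library(ductr)
spec <- phantom_spec(n_generations = 3, length_per_generation = c(1.2, 0.8, 0.6),
                     companion_gap_mm = 0.1, seed = 42)
dp  <- make_dual_phantom(spec)      # PV tree + BD companion at 0.1 mm gap
cfg <- pipeline_config(dp$grid_bd, dp$grid_pv,
                       bd_origin_mm = dp$truth_bd$origin_mm,
                       pv_origin_mm = dp$truth_pv$origin_mm,
                       out_dir = "example_out")
s <- run_pipeline(cfg)
```

This prints/returns (abridged):

```
PV volume: 0.02508 mm^3   BD volume: 0.00299 mm^3   BD:PV = 0.119
PV curved 5.420 mm, chord 5.219 mm, tortuosity 3.84%
furcations (PV): 3 bifurcations
max BD-PV gap: 0.096 mm (programmed 0.1)

  region generations   size_mm mean_branch_length_mm branch_count branch_percent
1     R1         1-1 1.2323961             1.2323961            1       14.28571
2     R2         2-2 0.8521729             0.8521729            2       28.57143
3     R3         3-3 0.6208264             0.6208264            4       57.14286
```

Reading it: the BD:PV volume ratio 0.119 ≈ 1/9 follows from the programmed
1:3 radius ratio; the 3.84% whole-system tortuosity of a straight-branched
tree is the residual voxel-chain quantization (a genuinely tortuous duct
scores tens of percent — see the vignette); the recovered maximum gap
(0.096 mm) matches the programmed 0.1 mm to within a voxel; and the
region table reproduces the programmed per-generation lengths and the
1/2/4 branch counts. `example_out/` contains `summary.json`, node/link,
branch, region, diameter-profile and distance CSVs, and GraphML graphs.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/duct.R load    --mask bd.tif --voxel-size-um 12
Rscript inst/cli/duct.R phantom --out-dir fixtures --dual --seed 1
Rscript inst/cli/duct.R run     --config cfg.yaml
```

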