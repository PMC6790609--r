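# ocperfusion

Simulation of the steady culture microenvironment inside a
**dual-chamber perfusion bioreactor** holding an additively
manufactured **bilayered osteochondral scaffold** — and of how that
microenvironment shifts between the CAD design and the as-manufactured
part.

Osteochondral constructs pair cartilage, which wants near-quiescent
low-shear conditions, with bone, which responds to perfusion-induced
shear. A dual-chamber bioreactor perfuses chondrogenic medium over the
chondral half of one scaffold and osteogenic medium over the osseous
half; whether the construct actually sees an effective microenvironment
depends on quantities that are hard to measure and easy to simulate:
the velocity field inside the lattice, the fluid-induced shear stress
(FSS) on the struts, and how much of each medium leaks into the other
chamber. This package is for tissue-engineering groups who want those
quantities for a parametric scaffold/chamber design without a
commercial CFD stack, and who want to know how sensitive they are to
printing artifacts.

## What it computes

For a voxelized scaffold + chamber geometry the package solves the
unified **Stokes–Brinkman** system (creeping flow; one momentum
equation with `k = 1e-12 m²` in the collagen-filled chondral pores and
a vanishing penalization permeability inside PLA struts),

```
mu lap(u) - grad p - (mu / k(x)) u = 0,    div u = 0,
```

then steady **advection–diffusion** of a normalized media tracer
(`D = 2.907e-9 m²/s`, hybrid upwind/central finite volumes, discrete
maximum principle guaranteed), and estimates **wall shear stress** on
strut surfaces from the fluid-side velocity gradient,
`tau = mu (4 u_t(h) - u_t(2h)) / (2h)`. Results are reported per
scaffold layer (mean/max velocity, mean/max FSS in mPa, mean
concentration) plus flux-weighted outlet mixing fractions, and
classified against literature culture-regime thresholds
(chondrogenesis: mean FSS < 0.1 mPa at ≤ 0.2 ml/min; osteogenesis:
0.05–100 mPa; cell detachment above 235 µm/s).

A **synthetic micro-CT pathway** closes the CAD-vs-manufactured loop:
seeded printing artifacts (strut diameter error, sag, roughness) →
grayscale rendering with partial-volume blur, noise and radial bias
(collagen is radiolucent) → 3-D bilateral smoothing → global Otsu
segmentation → the same solvers on the segmented geometry → a signed
percent-difference table against the CAD run.

## Worked example

A paired CAD/manufactured run at the desk-scale default resolution
(500 µm voxels, 0.02 ml/min per chamber, seed 1):

```r
library(ocperfusion)
res <- runPipeline(output_dir = "run1", seed = 1)
res$cad$report
#> MicroenvReport
#>     layer mean_v_um_s max_v_um_s mean_fss_mpa max_fss_mpa mean_conc
#>  chondral    0.000633    0.01204     0.004233      0.5271   0.95422
#>   osseous    4.440302   90.66272     0.011050      0.2598   0.02363
#> outlet mixing: top 1.4%, bottom 1.4%
```

Reading it: inside the collagen-filled chondral layer the medium is
nearly stagnant (sub-µm/s superficial velocity) while its mean tracer
concentration stays at 0.95 — the chondral layer is fed by its own
medium essentially undiluted. The open osseous lattice sees µm/s-scale
interstitial flow with ~90 µm/s peaks near the inlets, far below the
235 µm/s detachment threshold. Mean FSS in both layers stays well
below the 0.1 mPa chondrogenic ceiling at this resolution, so the
verdict

```r
res$verdict
#> RegimeVerdict (flow 0.02 ml/min)
#>     layer chondrogenic_compatible osteogenic_compatible detachment_risk
#>  chondral                    TRUE                 FALSE           FALSE
#>   osseous                    TRUE                 FALSE           FALSE
```

flags both layers as low-shear (chondrogenic-range) with no detachment
risk. The paired comparison shows the direction of the
manufactured-vs-CAD shift — the over-extruded (denser) osseous mesh
speeds up its interstitial flow while the chondral media supply barely
moves:

```r
subset(res$comparison, metric == "mean_v_um_s" | metric == "mean_conc")
#>       layer      metric        a        b pct_diff undefined
#> 1  chondral mean_v_um_s 0.000633 0.001244   96.592     FALSE
#> 5  chondral   mean_conc 0.954219 0.973943    2.067     FALSE
#> 6   osseous mean_v_um_s 4.440302 4.930531   11.040     FALSE
#> 10  osseous   mean_conc 0.023628 0.002283  -90.336     FALSE
```

(Numbers above are from the run shown; your exact values depend on the
seed through the artifact draws.) `run1/` contains the label TIFFs,
VTK fields for ParaView, report CSV/JSON and a provenance log.

A thin CLI wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/ocperfusion-run.R", package="ocperfusion"))') \
    run --config my.yaml --out run2 --seed 7
```

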