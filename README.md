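# SCMFusion

Pixel-level fusion of co-registered multimodal medical images (for
example a CT and an MR slice of the same anatomy) driven by a **spiking
cortical model** (SCM), for researchers working on image fusion and for
pipelines that need a deterministic, dependency-light fusion step with
built-in quality scoring.

## Method

Each pixel is an SCM neuron with leaky internal activity `F`, a leaky
dynamic threshold `Θ`, and a binary pulse output `Y`:

    F[n] = f·F[n−1] + O + O·(W ⋆ Y[n−1])
    Θ[n] = g·Θ[n−1] + h·Y[n−1]
    Y[n] = 1 where F[n] > Θ[n−1]

with `O` the normalized intensity and `W` the inverse-square linking
kernel over a 3×3 neighbourhood. Running `Nmax = 20` iterations on both
sources yields two pulse series and, by summation, two firing-mapping
images `T^A`, `T^B`. Three patch statistics (3×3 patches) then build the
fusion:

- local energy `E = Σ_patch T²` gates which source dominates each pixel;
- patchwise binary Shannon entropies of the pulse series, stacked over
  iterations, give the gray-level similarity
  `S_En = 1 − ‖V^A − V^B‖₂ / CS1`, `CS1 = 3·Nmax`;
- the Weber local descriptor differential excitation
  `ξ = arctan(Σ_patch (T_neigh − T_centre) / T_centre)` of the firing
  maps gives the structural similarity
  `S_WLD = 1 − |ξ^A − ξ^B| / CS2`, `CS2 = 5π`.

The fused image is the energy-gated convex combination with weight
`ω = S_En · S_WLD`:

    U = ω·I^A + (1−ω)·I^B   where E^A > E^B
    U = (1−ω)·I^A + ω·I^B   otherwise

Under the default constants every `ω ∈ (0.74, 1]`, so the locally more
energetic (more structured) source always carries the majority share.
The package also implements the six standard fusion-quality metrics —
mutual information `Q_M`, edge preservation `Q_E`, the SSIM-based index
`Q_S`, the fusion quality index `Q_L`, the fusion similarity metric
`Q_T`, and the standard deviation `STD` — plus a deterministic
synthetic phantom generator producing co-registered CT-like/MR-like
pairs, so everything is testable without external data. See the methods
vignette (`vignettes/scm-fusion-methods.Rmd`) for the full model
description and design notes.

## Worked example

```r
library(SCMFusion)

pair  <- makePair(seed = 7, size = 256)      # co-registered CT-like / MR-like
fused <- scmFuse(pair$ct, pair$mr)           # default FusionConfig()
show(fused)
#> FusedImage: 256 x 256 ; intensity range [ 0 , 232.32 ]

metricReport(pair$ct + 0, pair$mr + 0, fused)
#> MetricReport
#>   QM  (mutual information, bits): 5.6776
#>   QE  (edge preservation):        0.7638
#>   QS  (SSIM-based):               0.8777
#>   QL  (fusion quality index):     0.9051
#>   QT  (fusion similarity):        0.8219
#>   STD (contrast):                 70.0908
```

`QM` says the fused image retains about 5.7 bits of joint information
about the two sources; `QE`/`QS`/`QL`/`QT` (all with ideal value 1)
measure how much edge and structural content survived; `STD` is the
global contrast. For comparison, the naive pixelwise average of the
same pair scores QM 4.6458, QE 0.3958, QS 0.7004, QL 0.4252, QT 0.6795
and STD 42.7557 — lower on every axis, the washed-out-contrast failure
mode the weighted method is designed to avoid.

A command-line wrapper over the same functions is installed with the
package:

```sh
scmfuse=$(Rscript -e 'cat(system.file("scripts", "scmfuse", package = "SCMFusion"))')
Rscript $scmfuse synth --seed 7 --size 256 --out-dir demo/
Rscript $scmfuse fuse demo/ct.png demo/mr.png --out demo/fused.png
Rscript $scmfuse metrics demo/ct.png demo/mr.png demo/fused.png --json demo/report.json
```

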