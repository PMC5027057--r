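# fundusnc

Retinal fundus image enhancement by background suppression, for
researchers working on vessel segmentation, lesion detection or image
quality pipelines who need a reproducible, parameter-explicit
enhancement stage — plus the objective metrics to judge it and a seeded
phantom generator so everything is testable without downloading retinal
datasets.

## The method

Fundus photographs suffer from low vessel contrast and uneven
illumination, and direct contrast stretching (histogram equalization,
CLAHE) shifts color levels or creates artificial boundaries. This
package enhances by suppressing the background instead:

1. **Background estimation** — normalized convolution with a
   domain-transform box kernel. Each scanline is reparameterized by
   `ct[j] = ct[j-1] + 1 + (σs/σr) Σk |Ik(j) − Ik(j−1)|` and box-filtered
   in the transformed coordinate with per-pixel renormalization;
   iterated N times with shrinking radii
   `σ_H_i = σ_H √3 · 2^(N−i) / √(4^N − 1)`. At the working point
   (σs = 60, σr = 0.4) this averages vessels *into* the background,
   yielding a smooth background image J.
2. **Fusion** — `P = I − a(J − I) = (1+a) I − a J`, clipped to [0, 1],
   default a = 5: dark structures fall below their background estimate
   and are amplified downward, flat regions pass through.
3. **Two-stage denoising** — fourth-order PDE diffusion
   `∂P/∂t = −∇²[c(|∇²P|) ∇²P]` with `c(s) = 1/(1+(s/k)²)`, k = 1 on the
   byte scale (explicit Euler, dt = 0.1, 10 steps), then a relaxed
   median filter (3×3 window) that keeps each pixel lying within the
   [α-th, ω-th] order statistics of its window (α = 3, ω = 7) and
   replaces outliers with the window median.

Quality is quantified by the **contrast improvement index**
`CII = C_en / C` with `C = |f − b| / (f + b)` (mean vessel vs non-vessel
gray inside the field of view, green channel) and by the **linear index
of fuzziness** `r = 2/(MN) Σ min(p, 1−p)`,
`p = sin(π/2 (1 − f/f_max))` — larger CII and smaller r mean better
enhancement.

## Worked example

```r
library(fundusnc)

p <- generate_phantom(phantom_spec(seed = 1))   # 256x256 + ground truth
res <- enhance(p$image)                          # default working point
print(res)
#> Enhanced fundus image 256 x 256
#>   stage timings (s): nc 0.16, fusion 0.01, pde 0.10, rmf 0.21

enhancement_report(p$image, res$enhanced, p$vessel_mask, p$fov_mask,
                   fov_only = TRUE)
#> Enhancement quality report (green channel)
#>   contrast C (original):  0.0898
#>   contrast C (enhanced):  0.6005
#>   CII:                    6.6851
#>   fuzziness r (original): 0.5956
#>   fuzziness r (enhanced): 0.3085
```

The phantom's vessels start at a barely-visible contrast of 0.09; after
enhancement the vessel/background contrast inside the field of view is
0.60, a 6.7-fold improvement, while the fuzziness index drops from 0.60
to 0.31 — the image is both higher-contrast and crisper. The
intermediates (`res$background`, `res$fused`, `res$denoised_pde`) expose
each stage.

A command-line interface wraps the same functions:

```sh
exec/fundusnc synth --seed 7 --output-dir phantom/
exec/fundusnc enhance --input phantom/image.png --output enhanced.png
exec/fundusnc eval --input phantom/image.png --enhanced enhanced.png \
    --vessels phantom/vessels.png --fov phantom/fov.png --fov-only
exec/fundusnc sweep --input phantom/image.png --mode a --output-dir sweep/
```

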