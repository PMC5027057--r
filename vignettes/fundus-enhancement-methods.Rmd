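---
title: "Methods: background-suppression enhancement of fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background-suppression enhancement of fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusnc)
```

## The problem and the model

Color fundus photographs show retinal vessels, the optic disk and the
fovea inside a circular field of view (FOV) on a black surround. Uneven
illumination and low vessel/background contrast make direct contrast
stretching unreliable: global methods shift color levels, adaptive
histogram methods create artificial boundaries. This package instead
*suppresses the background*: it estimates a smooth background image $J$
from the original $I$, amplifies the difference, and cleans up the
amplified noise.

The chain is

$$I \;\xrightarrow{\text{normalized convolution}}\; J
  \;\xrightarrow{\;P = I - a(J - I)\;}\; P
  \;\xrightarrow{\text{4th-order PDE}}\; P_{\mathrm{pde}}
  \;\xrightarrow{\text{relaxed median}}\; \text{enhanced image}.$$

### Background estimation

`nc_smooth()` performs normalized convolution with a domain-transform box
kernel. Each scanline is reparameterized by

$$ct_1 = 0,\qquad
  ct_j = ct_{j-1} + 1 + \frac{\sigma_s}{\sigma_r}
  \sum_{k=1}^{3} |I_k(j) - I_k(j-1)|,$$

so distance accumulates faster across intensity edges, and the pixel is
replaced by the mean of all samples whose transformed coordinate lies
within a box radius — per-pixel renormalization by the window size makes
constants exact fixed points. Because $ct$ is monotone, each window is
contiguous and the filter runs in $O(n)$ per scanline with running sums
over bounds located by `findInterval()`; a test asserts agreement with
the direct $O(n^2)$ window enumeration to $10^{-9}$.

The filter is iterated $N$ times (rows then columns per iteration,
transforms recomputed from the current image each pass) with shrinking
box radii $r_i = \sqrt3\,\sigma_{H_i}$,

$$\sigma_{H_i} = \sigma_H\,\sqrt3\;\frac{2^{\,N-i}}{\sqrt{4^N - 1}},
  \qquad \sigma_H \equiv \sigma_s,$$

which conserves total variance ($\sum_i \sigma_{H_i}^2 = \sigma_H^2$) and
collapses to a single box of standard deviation $\sigma_H$ at $N = 1$.
With the working-point parameters $\sigma_s = 60$ px and
$\sigma_r = 0.4$ the kernel is wide enough in both space and range to
average vessels *into* the background — deliberately the opposite of the
edge-preserving regime this kernel family is usually used in.

Choices that the formulation leaves open, fixed here once: $N = 3$
(customary for iterated box approximations of a Gaussian); horizontal
before vertical passes; the three channels share a single transform
(channel-summed absolute differences) and are filtered with identical
windows; a length-1 scanline is returned unchanged.

### Fusion

`fuse()` computes $P = I - a(J - I) = (1+a)I - aJ$ and clips to $[0,1]$.
Dark structures (vessels, fovea, microaneurysms) fall below their local
background estimate and get pushed down by a factor $(1+a)$; flat regions
where $J \approx I$ are untouched. At the default $a = 5$ a substantial
fraction of pixels saturates; clipping (rather than min–max
renormalization) is used because saturation is exactly what an 8-bit
display of the result implies, and the clipping fraction can be logged
(`verbose = TRUE`). `a = 0` is the bit-exact identity.

### Two-stage denoising

Fusion amplifies noise by $(1+a)$, so the fused image is denoised twice.

**Fourth-order PDE.** Per channel on the byte scale,
$$\partial_t P = -\nabla^2\!\left[c(|\nabla^2 P|)\,\nabla^2 P\right],
  \qquad c(s) = \frac{1}{1 + (s/k)^2},$$
integrated by explicit Euler steps: `L` is the 5-point Laplacian with
replicate boundaries, `g = L / (1 + (|L|/k)^2)`, update
`P - dt * L(g)`. Driving the conductance with the *Laplacian* rather
than the gradient is what makes the scheme fourth-order and free of the
staircasing of second-order diffusion: smooth regions (small $|L|$)
diffuse, oscillatory noise and edges (large $|L|$) are protected.

The conductance constant is $k = 1$ *on the byte scale* $[0,255]$ — on
the unit scale $k = 1$ would make $c \approx 1$ everywhere and degrade
the scheme to linear fourth-order diffusion, so the package converts to
bytes for this stage only. The integration constants are not dictated by
the formulation; the package uses $dt = 0.1$ with 10 steps and guards
$dt \le 0.25$ for stability of the explicit fourth-order stencil.
Constants and planar ramps are fixed points; the divergence form
preserves the mean of interior-supported perturbations (both tested).

**Relaxed median.** Per channel and pixel, the $n^2$ samples of the
square window (replicate boundary, default $3\times3$) are sorted; the
center value is kept when it lies within the $[\alpha$-th, $\omega$-th$]$
order statistics inclusive and replaced by the window median otherwise.
$\alpha = 1, \omega = n^2$ is the identity; $\alpha = \omega$ at the
median index is the classical median filter. The window size and band
are not fixed by the formulation; the package defaults to the symmetric
mid-band $\alpha = 3$, $\omega = 7$ of 9 samples, the standard choice
for this filter family. The implementation sorts all windows at once
with a vectorized odd–even transposition network and is tested against a
per-pixel sort oracle over the full $(\alpha, \omega)$ grid.

## Objective metrics

`vessel_contrast()` computes $C = |f - b|/(f + b)$ with $f$, $b$ the
mean gray values over vessel and non-vessel pixels *inside the FOV* (the
black surround is excluded), and `cii()` the contrast improvement index
$\mathrm{CII} = C_{\text{en}}/C$. The magnitude is used because dark
vessels make the signed ratio negative while the index is conventionally
reported positive. Evaluation uses the green channel, where vessel
contrast is highest.

`fuzziness()` maps each pixel to a membership
$p = \sin\!\big(\tfrac{\pi}{2}(1 - f/f_{\max})\big)$ and returns
$r = \tfrac{2}{MN}\sum \min(p, 1-p) \in [0,1]$ — the mean closeness of
memberships to the maximally ambiguous 0.5. Crisp images (pixels at 0 or
$f_{\max}$) score 0. By convention $r$ is computed over the whole
$M \times N$ image including the surround, with $f_{\max}$ the image
maximum; `fov = mask` restricts both to the field of view, which is the
more meaningful comparison on phantoms whose surround is exactly zero.

## The synthetic phantom

`generate_phantom()` renders a seeded fundus-like test image with exact
ground truth: a circular FOV on black; a reddish base modulated by
radial vignetting plus a random low-frequency illumination field; a
vessel tree grown by seeded branching random walks from the optic-disk
region, widths tapering 4 px to 1 px, darkened most strongly in green;
an optional bright optic disk and dark fovea; Gaussian blur
($\sigma = 1$ px) on the vessel indicator for soft edges; additive
Gaussian noise inside the FOV. The vessel mask records the pre-blur
support. All randomness comes from one private stream seeded by
`spec$seed`, so phantoms are bitwise reproducible and the caller's RNG
state is never touched.

Defaults (chosen once as fundus-realistic and then frozen): 256×256,
FOV radius 0.46 of the short side, 5 vessel roots giving an 8–12%
vessel fraction of the FOV, vessel contrast dip 0.15, illumination
amplitude 0.25, noise σ 0.02. One deliberate coupling: the radial
vignette is scaled by `illumination_amplitude`, so amplitude 0 yields a
perfectly flat background — that makes "invisible vessels at zero
contrast" an exact identity instead of an approximate one, which is the
property the generator's tests pin down.

What the phantom does *not* emulate: pathology (exudates, hemorrhages),
texture of the neural fiber layer, chromatic aberration, realistic
vascular branching statistics. Tests passing on phantoms therefore
demonstrate the pipeline's mechanics and direction of effect (CII > 1,
fuzziness decreases), not clinical performance on real datasets.

## Numerical choices and degenerate inputs

* Canonical intensity range is the unit interval; the byte scale appears
  only inside the PDE stage (where $k = 1$ demands it) and at 8-bit file
  I/O (values clipped, scaled by 255, rounded half-up).
* Images are plain `H x W x 3` arrays indexed `[row, column, channel]`
  with row 1 at top, matching raster file order and R convention.
* Window membership in the box filter and the order-statistic band are
  both inclusive.
* FOV estimation thresholds the per-pixel channel maximum at 0.06 on the
  unit scale (DRIVE-style surrounds are near zero), then applies a
  morphological closing (disk radius 3) and hole filling.
* Degenerate inputs fail loudly: empty scanlines, non-positive box
  radii, all-zero images for the fuzziness index ($f_{\max} = 0$), empty
  vessel or background regions, and $C = 0$ originals for the CII.

## Problem sizes

The test suite exercises scanlines up to $n = 256$ against the
brute-force oracle, 16×16 images over the full relaxed-median parameter
grid, 256×256 phantoms for the end-to-end direction-of-effect checks,
and one 584×565 phantom (the DRIVE image geometry) for the full
pipeline. These sizes were chosen so the whole suite runs in well under
a minute while still covering every code path at realistic image
dimensions.

## Known limitations

* The full enhancement is not idempotent and has no convergence
  guarantee in $a$; very large $a$ saturates most of the FOV.
* The PDE stage's explicit scheme needs many steps for strong noise;
  no implicit or adaptive stepping is provided.
* CII depends on the vessel mask; on real data it requires a manual
  segmentation, and on phantoms it uses the generator's ground truth.
* Only RGB rasters are supported; no DICOM or proprietary fundus
  formats.
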