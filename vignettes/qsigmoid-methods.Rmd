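---
title: "Methods: q-sigmoid intensity transforms and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: q-sigmoid intensity transforms and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsigmoid)
```

## The model

The package enhances a region of interest in a grayscale image
$I : D \to [0, L]$ by mapping each pixel through a bell-shaped transfer
curve that peaks at a target intensity $\beta$ and decays with the
scaled deviation $u = |I - \beta| / \alpha$. Two classical kernels are
provided:

* the **bell sigmoid** $I_1 = 2 / (1 + e^{\lambda u})$, with background
  asymptote 0, and
* the **modified sigmoid** $I_2 = 1 / (1 + e^{-\lambda / u})$ for
  $I \ne \beta$ (value 1 at $\beta$), whose reciprocal exponent gives a
  flat peak and a background asymptote of $1/2$.

Replacing the exponential with the Tsallis q-exponential

$$\exp_q(x) = [1 + (1-q)x]^{1/(1-q)} \quad (0 \text{ where the base is} \le 0)$$

yields the **q-sigmoid** family with one extra degree of freedom, the
entropic index $q \ge 0$:

* `qsig_low` $= 2 / (1 + \exp_q(\lambda u))$, intended for $q < 1$. Its
  tail is heavier than the classical sigmoid's, it dominates it
  pointwise, and it is non-increasing in $q$ — smaller $q$ highlights a
  wider intensity band around $\beta$.
* `qsig_high` $= 1 / (1 + \exp_q(-\lambda/u))$, intended for $q > 1$.
  Its deformed base $1 + \lambda(q-1)/u$ exceeds 1 everywhere off the
  peak, the value decays to $1/2$ in the tails, and — since
  $(1 + a/n)^n$ increases in $n$ — the value is *strictly decreasing in
  q* at every $I \ne \beta$: larger $q$ flattens the whole curve toward
  $1/2$.

Both deformations recover their classical limits as $q \to 1$; indices
within $10^{-9}$ of 1 are computed with the classical closed forms to
avoid the $1/(1-q)$ blow-up. The deformed power itself is evaluated as
$\exp(\mathrm{log1p}((1-q)x)/(1-q))$; overflow and underflow land on
the correct limits (0 or 1) of the surrounding sigmoid.

### Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `beta` | intensity mapped to 1 (the band center) | image intensity | — |
| `alpha` | half-width of the highlighted band, $> 0$ | image intensity | — |
| `lam` | gain: peak decay is $\approx \lambda/(2\alpha)$ per intensity unit | dimensionless | 1 |
| `q` | entropic index; 1 restores classical kernels | dimensionless | 1 |

`beta` and `alpha` must be on the image's own scale; the package leaves
intensity scaling to the caller because practitioners mix `[0, 255]`
and `[0, 1]` conventions freely. For `[0, 1]` images, `lam = 1` is a
sensible starting gain.

Out-of-intent index ranges are opt-in (`extend = TRUE`): `qsig_low`
with $q > 1$ maps cutoff pixels to 0 (the one-sided limit of the
expression), and `qsig_high` with $q < 1$ applies the literal
q-exponential cutoff near the peak, giving value 1 there. These
extensions exist because published parameterizations occasionally pair
the $1/2$-background form with sub-unit indices.

## Analytic calculus

`analytic_derivative()` implements the closed-form derivatives of all
four kernels for $I > \beta$ and uses the sign-flipped expressions for
$I < \beta$ (every kernel is even about $\beta$). At the peak the bell
sigmoid and `qsig_low` have one-sided slope $-\lambda/(2\alpha)$ —
*independent of q*; by convention the function reports that value at
$I = \beta$ tagged `side = "right"`. The flat-peak kernels have no
closed form at $\beta$, so evaluation there is an error pointing to
`difference_quotient_d()`, the forward-quotient probe whose magnitude
decays to 0 at the peak for moderate $q$.

Two of the printed source formulas required re-derivation: the leading
coefficient of the `qsig_low` derivative must be $-2\lambda/\alpha$
(only then does the peak limit $-\lambda/(2\alpha)$ follow), and the
$(1+e^g)$ factor in the modified-sigmoid derivative carries exponent
$-2$. Both forms are pinned by the finite-difference oracle tests at
relative tolerance $10^{-6}$.

`taylor_ratio_r()` quantifies how nearly linear the `qsig_low` peak
decay is: the ratio of the exact kernel to its first-order
approximation $1 - \frac{\lambda}{2\alpha}(I - \beta)$ stays below
about 1.07 at $I = \beta + \alpha/2$ for all $q \in (0,1)$ at
$\lambda = 1$ (the package computes 1.0662, attained as $q \to 0$).

## Synthetic study conditions

`gaussian_scene()` builds the reference phantom: a 256×256 raster with
a radial Gaussian of spread 30 px centered at pixel (175, 175),
amplitude normalized to exactly 1. The printed source is ambiguous
about whether its "mean 175 / variance 30" are spatial or intensity
statistics and whether 30 is a variance; this package reads them as the
spatial center and a standard deviation in pixels (the visible extent
of the original figure supports 30 as a length scale), and both
readings remain configurable (`delta_is_variance`,
`ground_truth_mask(mode = "intensity")`).

The ground-truth region is the $3\delta$ disc about the center (radius
90 px, clipped at the raster border). `add_gaussian_noise()` uses the
linear power-ratio SNR convention, $\sigma^2 = \overline{I^2} /
\mathrm{SNR}$, clipping (not wrapping) to $[0, L]$; a nominal SNR of 0
in a series is mapped to the smallest positive value, since zero SNR is
degenerate. `speckled_lesion_scene()` is a qualitative ultrasound
stand-in — a dark ellipse under unit-mean gamma speckle with shape
`looks` — not a physical speckle simulation; it exists so the batch
experiments run on data with the right gross structure (dark lesion,
multiplicative noise). All generators are pure functions of their
arguments and seed.

## Evaluation statistics

* **Err** $= 1 - A_1/A_0$ compares convex-hull areas of the achieved
  and ground-truth regions. Hull area is the shoelace area of the hull
  polygon over pixel *centers* (a pixel-count variant is available for
  sensitivity checks), and Err is deliberately not clamped: an achieved
  hull larger than the truth goes negative.
* **AMBE** $= |\bar X - \bar Y|$ measures brightness preservation.
* **S** averages the Jaccard index with the fraction of the one-pixel
  dilation ring of the truth left uncovered — the ring term penalizes
  segmentations that bridge the region border. Dilation uses the full
  3×3 structuring element with outside-as-background borders.

The source never states how an "achieved region" is extracted from a
filtered image, so extraction is this package's own convention,
recorded with every result: threshold at 0.5 for the 0-background
kernels and 0.75 for the $1/2$-background kernels (the midpoint between
background and peak), optionally keeping only the largest 8-connected
component.

## What the experiments can and cannot reproduce

`run_err_grid()` reproduces the *direction* of the published phantom
trends, and those directions follow rigorously from pointwise ordering
plus hull monotonicity:

* Err is non-increasing in $\alpha$ at fixed $q$ (wider band, larger
  region);
* for the heavy-tail family, Err is non-decreasing in $q$ on $(0, 1]$
  (the $q$-ordering of the kernel makes each region a subset of the
  next).

The published *absolute* Err values are not reproducible: they depend
on the unstated extraction rule, and the original tables are internally
inconsistent between repeats of the same cell. More importantly, the
published claim that the $1/2$-background family at $q > 1$ matches or
beats its $q = 1$ limit cannot hold under any fixed-threshold
extraction: the kernel is strictly decreasing in $q$ off the peak, so
the extracted region contracts and Err can only grow with $q$. The
package asserts the true (contraction) ordering in its unit tests and
keeps the opposite direction as an intentionally failing check in the
acceptance suite, documenting the discrepancy rather than tuning the
protocol around it.

Similarly, Otsu after q-sigmoid preprocessing on the clean phantom
scores $S \approx 0.61$ against the $3\delta$-disc truth (the Otsu
region of the filtered phantom has radius ≈ 41 px versus the truth's
90 px), not a near-perfect score; the original similarity figures used
a trained CNN segmenter, which is out of scope here.
`run_noise_similarity()` therefore reports the paired raw/preprocessed
scores without asserting which is larger.

## Numerical and design choices

* Otsu uses a fixed 256-bin histogram with bins
  $\lfloor v/L \cdot (n_{\text{bins}}-1) \rfloor$ regardless of bit
  depth, ties broken toward the lower threshold — bit-exact across 8-
  and 16-bit inputs, and verified against an exhaustive between-class
  variance search.
* Slicing's window is unspecified in the source; the default is the
  2nd–98th percentile window with clamping, matching the stated intent
  of excluding the extreme intensity ranges.
* Degenerate inputs fail loudly: constant images for Otsu, empty truth
  or raster-filling truth for S, zero-area truth hulls for Err,
  evaluation at $\beta$ for the flat-peak derivatives.
* Problem sizes in the test suite follow the study conditions (256×256
  phantom, the $\alpha \in \{0.01, \dots, 0.03\}$ ×
  $q \in \{0.7, \dots, 1.2\}$ grid); the batch experiments are
  exercised on a handful of seeded speckle scenes, which is enough to
  pin the statistics' identities and determinism.

## Known limitations

* The speckle generator is qualitative; conclusions about real
  ultrasound require real scans.
* `add_gaussian_noise()` seeds the global RNG stream (R's conventional
  but stateful mechanism).
* The histogram-matching route to automatic parameter selection that
  the source sketches as future work is not implemented; parameters are
  chosen by the user, typically by scanning a small $q$ sequence around
  1.
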