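# qsigmoid

Region-of-interest enhancement for grayscale images with **q-sigmoid**
intensity transforms — bell-shaped transfer curves built on the Tsallis
q-exponential — together with the statistics used to evaluate such
enhancers and seeded synthetic scenes to test them on. The intended
users are image-analysis practitioners (ultrasound and other
speckle-heavy modalities in particular) who want a parametric,
reproducible way to highlight an intensity band ahead of thresholding
or segmentation.

## The transforms

A transform is parameterized by the target intensity β (mapped to 1),
the band half-width α > 0, the gain λ > 0 and the entropic index
q ≥ 0. With u = |I − β| / α and the q-exponential
exp_q(x) = [1 + (1−q)x]^(1/(1−q)) (0 where the base is ≤ 0):

| family | formula | background | intended q |
|---|---|---|---|
| `sigmoid` | 2 / (1 + exp(λu)) | 0 | q = 1 |
| `modified_sigmoid` | 1 / (1 + exp(−λ/u)) | 1/2 | q = 1 |
| `qsig_low` | 2 / (1 + exp_q(λu)) | 0 | q < 1 |
| `qsig_high` | 1 / (1 + exp_q(−λ/u)) | 1/2 | q > 1 |

Every family equals exactly 1 at I = β and is symmetric about β. For
q < 1 the tail is heavier than the classical sigmoid's (a wider band is
highlighted); for q > 1 the curve flattens toward 1/2. Both recover the
classical forms as q → 1. The package also provides the closed-form
derivatives and their one-sided peak limits (−λ/2α for the 0-background
kernels), the Taylor-ratio and difference-quotient diagnostics, the
evaluation statistics Err / AMBE / S, the baseline enhancers
(histogram equalization, slicing, Otsu), and seeded phantom /
speckled-lesion generators.

## Worked example

Highlight the mid-bright band of the synthetic Gaussian phantom and
score the extracted region:

```r
library(qsigmoid)

p <- transform_params(beta = 0.6, alpha = 0.1, lam = 1, q = 0.5)
p
#> <transform_params beta=0.6 alpha=0.1 lam=1 q=0.5 family=auto -> qsig_low>

img <- gaussian_scene()                 # 256x256, peak 1 at (175, 175)
out <- apply_transform(img, p)
out
#> <gray_image 256x256, L = 1, range [0.1176, 0.9958]>
#>   produced by family: qsig_low

m <- extract_region(out, largest_component = TRUE)
m
#> <region_mask 256x256, 2828 pixels set>

err_measure(m, ground_truth_mask(gaussian_scene_spec()))
#> [1] 0.8194388
ambe(img, out)
#> [1] 0.08125075
```

The transform maps the annulus of phantom pixels near intensity 0.6 to
bright values (2828 pixels survive the 0.5 threshold). Err = 0.82 says
the convex hull of that region covers about 18% of the ground-truth
disc's hull — β was aimed at a mid-intensity ring, not the full 3σ
disc. AMBE = 0.081 is the absolute change in mean brightness the
enhancement introduced.

Grid experiments reproduce the qualitative behavior of the transform
family on the phantom — error falls as the band widens (α ↑) and rises
as q → 1 (the heavy tail helps):

```r
run_err_grid(alphas = c(0.02, 0.03), qs = c(0.7, 1.0))
#>   alpha   q   family threshold       err error_message
#> 1  0.02 0.7 qsig_low       0.5 0.9948458
#> 2  0.02 1.0  sigmoid       0.5 0.9955821
#> 3  0.03 0.7 qsig_low       0.5 0.9917369
#> 4  0.03 1.0  sigmoid       0.5 0.9932913
```

A command-line front end covering enhancement, fixture generation,
metrics and the batch experiments ships at `inst/scripts/qsig.R`
(`Rscript inst/scripts/qsig.R enhance --in scan.png --out enh.png
--beta 0.15 --alpha 0.03 --q 2 --normalize`).

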