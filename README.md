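# WMIdetect

Automatic detection of punctate white matter injury (WMI) in 2D
T1-weighted MRI slices of very preterm neonates, for image-analysis
researchers and for clinical pipelines that already have a white-matter
delineation. WMI is bright on early T1 imaging but overlaps normal white
matter in absolute intensity; its reliable signature is an *abrupt*
intensity change against neighbouring tissue. WMIdetect finds those
changes with a stochastic transition model, then grows lesion regions from
them, and ships the evaluation machinery (accuracy-distance histograms,
Bland–Altman agreement) and a synthetic phantom generator needed to test
every stage without patient data.

## The model

White-matter intensities are histogram-stretched and quantized into
states $\{s_0,\dots,s_N\}$ ($N+1$ equal-width bins). For an 8-connected
pixel pair whose brighter member is $k$ states above its neighbour, the
model assigns probability

$$P(\text{drop of }k) = q\,\alpha^k,\qquad k=0,\dots,N,$$

where $q$ is the probability that adjacent pixels share a state
(estimated from the slice) and $\alpha$ is fixed by normalization as the
unique root in $(0,1)$ of

$$q\,\alpha^{N+1}-\alpha+(1-q)=0 .$$

Pairs whose drop probability falls below a threshold (default 0.01) mark
injury boundaries; boundaries hugging the white-matter margin are
discarded; regions grow from the bright side of each boundary by a
mean/sd similarity rule. See the methods vignette
(`vignettes/wmi-detection-methods.Rmd`) for the full account.

## Worked example

```r
library(WMIdetect)

# the transition law at q = 0.8, N = 3
m <- transitionModel(0.8, 3)
m
#> TransitionModel: q = 0.8 , alpha = 0.201314 , N = 3
#>   drop-size probabilities: 0.80000 0.16105 0.03242 0.00653
significantTransitions(m, 0.01)
#>   from to drop        prob
#> 1    3  0    3 0.006526972
```

Only the full drop `s3 -> s0` (probability 0.0065) is rarer than 1%: in a
4-state model fitted with q = 0.8, a pixel must jump the entire intensity
range of the white matter before the model calls it an injury boundary.

```r
# a synthetic slice with two known lesions, then detection
ph <- generatePhantom(phantomSpec(
  lesions = list(lesionSpec(c(60, 60), 4), lesionSpec(c(72, 72), 3)),
  seed = 17))
det <- detectWMI(ph$image, ph$wmMask)
det
#> WMI detection: q = 0.94 (estimated) | alpha = 0.05999 | threshold = 0.01
#>    48 seed(s) -> 2 component(s), 75 px total
componentTable(det$lesions)
#>   label areaPx centroidRow centroidCol
#> 1     1     46    59.95652    59.97826
#> 2     2     29    72.00000    72.00000
accuracyDistanceHistogram(det$lesions, ph$truthMask)
#>   distance count
#> 1        0    75
```

Both injected lesions are recovered as separate components centred on the
true lesion centres, and every one of the 75 detected pixels lies inside
the 78-pixel ground truth (distance 0) — the detector tracks the bright
lesion core and tends to under-cover the truth slightly, which is why the
Bland–Altman convention `reference - automatic` is used for area
agreement:

```r
blandAltman(c(1.0, 2.0), c(1.2, 2.6))
#> Bland-Altman agreement over 2 cases
#>   bias (reference - automatic): 0.4 cm^2
#>   limits of agreement: -0.1544 to 0.9544 cm^2
```

## Command-line interface

A thin CLI over the same functions lives at
`inst/scripts/wmi-cli.R` (installed under
`system.file("scripts", "wmi-cli.R", package = "WMIdetect")`):

```sh
Rscript wmi-cli.R fit      --q 0.8 --n 3 --threshold 0.01
Rscript wmi-cli.R phantom  --out out/ --seed 1 --lesions 2
Rscript wmi-cli.R detect   --image out/phantom_image.png \
                           --mask out/phantom_wm_mask.png \
                           --spacing 1,1 --out out/det
Rscript wmi-cli.R evaluate --detected out/det/wmi_mask.png \
                           --truth out/phantom_truth_mask.png --out out/eval
```

Inputs may be NIfTI volumes (slice index + header spacing) or PNG/TIFF
slices (spacing supplied); outputs are PNG/NIfTI masks, JSON reports
embedding the full configuration, and CSV evaluation tables.

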