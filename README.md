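# hippovol

Structural-MRI volumetry and hippocampus morphometry for early Alzheimer's
disease (AD) screening, with a majority-voting classifier ensemble — plus a
synthetic brain-slice phantom generator so the whole pipeline can be
exercised, tested and benchmarked without access to clinical imaging data.

## The problem and the method

Hippocampal shrinkage and grey-matter loss are among the earliest structural
biomarkers of AD. Given a skull-stripped, spatially normalized coronal
T1-weighted slice, `hippovol` computes five features per subject and
classifies the subject as patient or control:

**Tissue volumetry.** A gray-level range *thresh* = [lo, hi] brackets grey
matter (GM). Each in-brain pixel f(i, j) is classified by a three-way rule —
below the range: cerebrospinal fluid (CSF); inside: GM; above: white matter
(WM) — and per-class pixel counts, summed over slices, give

    Volume_WM  = Σ_slices Σ_i Σ_j [ f(i,j) > hi ]
    Volume_GM  = Σ_slices Σ_i Σ_j [ lo ≤ f(i,j) ≤ hi ]
    Volume_CSF = Σ_slices Σ_i Σ_j [ f(i,j) < lo ]

The range can be supplied manually or estimated by exhaustive three-class
between-class-variance maximization (a three-class Otsu criterion).

**Hippocampal area.** In the normalized 498×498 coronal frame the left and
right hippocampi are bounded by fixed rectangles with corners
(130, 300)–(225, 360) and (280, 300)–(375, 360) (column, row; 0-based,
half-open). Within each rectangle the chain is: extract ROI → binarize at
*lo* → morphological opening (disc, radius 1) → keep the largest
8-connected object → trim to its padded bounding box → separate GM-range
pixels → count them. The two areas (left, right) complete the feature
vector.

**Classification.** Three base classifiers — an RBF-kernel SVM with C and γ
tuned by inner cross-validated grid search, a 2-hidden-layer × 3-neuron
multilayer perceptron (backpropagation, learning rate 0.3), and a pruned
univariate decision tree with entropy splits (confidence factor 0.25
analogue) — vote on each subject, and the ensemble decides by majority:

    class = +1 (AD)   if  #{+1 votes} > n/2
            −1 (control) otherwise

Evaluation is stratified 10-fold cross-validation with pooled confusion
counts, reported as accuracy, specificity and sensitivity.

## Worked example

```r
library(hippovol)

# one noisy synthetic slice with known ground truth
sl <- generate_slice(phantom_spec(noise_sd = 8), seed = 1)
sl
#> <phantom_slice> 498x498, hippo areas L/R = 752/752 px, label = NA

th <- estimate_thresh(sl$image)
th
#> <thresh_range> GM in [85.006, 140.215]

tissue_volumes(segment_tissues(sl$image, th))
#> # A tibble: 1 × 4
#>   vol_gm vol_wm vol_csf n_slices
#> 1  39801  99636   26759        1

measure_hippocampi(sl$image, th)
#> # A tibble: 2 × 2
#>   side   area
#> 1 left    752
#> 2 right   750

# a 24-subject cohort, features, and cross-validated classification
cohort   <- generate_cohort(cohort_spec(n_ad = 12, n_control = 12, seed = 1),
                            phantom_spec(noise_sd = 8))
features <- extract_features(cohort)
report   <- crossvalidate(features, k = 6, seed = 1, subset = "left")
tidy(report)
#> # A tibble: 4 × 8
#>   classifier    tp    fn    tn    fp accuracy specificity sensitivity
#> 1 svm           12     0    12     0      100         100         100
#> 2 mlp           12     0    12     0      100         100         100
#> 3 tree          12     0    12     0      100         100         100
#> 4 ensemble      12     0    12     0      100         100         100
```

The painted hippocampus covers 752 pixels; the pipeline recovers 752 on the
left and 750 on the right despite noise of sd 8 — an error well under 1%.
The estimated GM range [85, 140] falls between the phantom's tissue means
(CSF 60 < GM 110 < WM 170), as it should. On this strongly atrophic
synthetic cohort (AD subjects simulated with mean atrophy 0.3 versus 0.05
for controls) every classifier separates the groups perfectly; real MRI
data is far harder, and the synthetic result only demonstrates that the
chain is wired correctly end to end.

A command-line front end lives at `inst/cli/hippovol.R`
(`simulate | segment | extract | classify | evaluate | run`), e.g.

```sh
Rscript inst/cli/hippovol.R simulate --n-ad 10 --n-control 10 --out cohort_dir
Rscript inst/cli/hippovol.R run --input cohort_dir --subset left --out results_dir
```

## Vignette

`vignettes/hippovol-methods.Rmd` documents the model and its assumptions,
the phantom's geometry and what it does and does not emulate, every tunable
parameter with its default and rationale, and the package's numerical
conventions.
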