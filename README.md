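# linkehr

Record linkage for deidentified electronic health record (EHR) cohorts,
with a simulation framework that lets linkage methods be validated against
known ground truth before they are trusted on real data.

## The problem

Two EHR extracts — say, a hospital's multiple sclerosis cohort and its
deidentified representation in a national registry — describe overlapping
patients but share no unique identifier. Linkage must rely on indirect
fields (sex, date of birth, nationality, region, coverage, facility, first
MS diagnosis date, and set-valued histories of other diagnoses,
medications, and admissions), and because the real pairing has no
reference standard, method performance cannot be measured on it directly.
`linkehr` addresses this for epidemiologists and health-data engineers by

1. generating a **synthetic two-source cohort** with known truth links and
   configurable per-field corruption, missingness and value-frequency skew;
2. implementing the **clone-and-deidentify simulation**: link a dataset to
   a value-identical copy of itself under fresh ids, so every true match is
   known and a full confusion matrix (sensitivity, PPV, F1, Wilson 95% CIs)
   can be computed for any method;
3. providing three linkage engines behind one evaluation surface:
   * **deterministic** — exact agreement on every field of a rule,
     implemented as a hash join;
   * **probabilistic (Fellegi–Sunter)** — blocking, binary comparison
     vectors, EM-estimated m/u-probabilities, summed log2
     likelihood-ratio scores `S = Σ_k [γ_k log2(m_k/u_k) +
     (1−γ_k) log2((1−m_k)/(1−u_k))]`, threshold and one-to-one
     classification;
   * **machine learning** — similarity features (exact agreement, date
     proximity `1/(1+|Δdays|)`, Jaccard) classified by knn, logistic
     regression, a neural network, or a random forest, with stratified
     75/25 evaluation and bootstrap confidence intervals.

## Worked example

Generate a 500-record cohort, clone and deidentify it, sweep every
variable as a one-field deterministic rule, then run the full
probabilistic pipeline:

```r
library(linkehr)
co <- generate_cohort(cohort_config(n_source_a = 500, seed = 42))
cl <- clone_deidentify(co$A)

single_variable_sweep(co$A, cl$clone, cl$truth)[,
  c("field", "candidate_pairs", "sensitivity", "ppv", "f1")]
#>                field candidate_pairs sensitivity   ppv    f1
#>  1:              sex          142672         100  0.35  0.70
#>  2:      nationality          242128         100  0.21  0.41
#>  ...
#>  6:              dob             522         100 95.79 97.85
#>  7: ms_first_dx_date             606         100 82.51 90.42
```

Every field reaches sensitivity 100% — on an uncorrupted clone each record
agrees with its copy on everything — but PPV exposes how identifying each
variable is: near-unique dates of birth produce 522 candidate pairs and
95.79% precision, while sex produces 142,672 coincidental candidates and
0.35%.

```r
res <- probabilistic_link(co$A, cl$clone, block = "dob",
  compare = c("sex", "nationality", "coverage", "facility",
              "region", "ms_first_dx_date"))
res$model
#> <fs_model> lambda = 0.9579, 4 EM iterations
#>               field     m      u w_agree w_disagree
#> 1:              sex     1 0.5455   0.874    -18.794
#> 2:      nationality     1 1.0000   0.000      0.000
#> ...
#> 6: ms_first_dx_date     1 0.0000  19.932    -19.932

confusion_from_pairs(res$pairs, cl$truth,
                     validate_pair_universe(co$A, cl$clone))
#> <confusion_metrics> TP 500 FP 0 FN 0 TN 249,500 (universe 250,000)
#>   sensitivity 100.00%  PPV 100.00%  specificity 100.00%  accuracy 100.00%  F1 100.00%
```

EM learns, from the unlabeled candidate pairs alone, that agreement on the
MS diagnosis date is worth ~20 bits while agreement on nationality
(dominated by one value within these blocks) is worth nothing; one-to-one
assignment then recovers the truth exactly.

## The analysis workflow

The numbered scripts under `analysis/` run the full comparative experiment
and write tables beneath `results/`:

| script | what it does |
|---|---|
| `01_generate_cohort.R` | clean (2642/2247 records) and corrupted cohorts with truth |
| `02_deterministic.R` | per-variable sweep and multi-field rules on the clone |
| `03_probabilistic.R` | EM models, threshold vs one-to-one classification |
| `04_ml.R` | both ML modes, four algorithm families, 100-rep bootstrap |
| `05_real_world.R` | truth-free match-count comparison on the corrupted pair |

The methods vignette (`vignettes/linkage-methods.Rmd`) documents the
model, conventions (missingness, set agreement, rounding), generator
calibration and known limitations.

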