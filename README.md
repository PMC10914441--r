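# brainchart

Lifespan brain charts and atrophy staging from cross-sectional
volumetry.

Neurodegenerative diseases such as progressive supranuclear palsy,
Richardson syndrome (PSP-RS) are only imaged years after
neurodegeneration begins, so the early anatomy of the disease cannot be
observed directly. `brainchart` infers it statistically from
cross-sectional volumetric tables: it fits normative lifespan
trajectories ("brain charts") of brain-structure volumes in healthy
controls, fits matching disease trajectories constrained over the whole
lifespan by pooling patients with all controls younger than the
youngest patient, detects the age at which the two trajectories' 95%
confidence bands stop overlapping, and orders those divergence onsets
into an anatomical staging timeline. It is aimed at neuroimaging
researchers who already have per-subject segmentation volumes (e.g.
whole-brain segmentations with left/right labels) and want a
reproducible staging analysis plus the simulation machinery to validate
it.

## The model

For each structure, volumes are summed across hemispheres, normalized
to total intracranial volume (v = 100·raw/TIV), and z-scored against
the control sample. Per group, candidate polynomials in age

  z = β₀ + β₁a + … + β_k a^k + ε,  k ∈ {1, 2, 3}

are fitted by OLS; a candidate is eligible when its F test against the
constant model and all its coefficient t tests are significant at
P < 0.05, and the eligible candidate with the lowest BIC
(n·ln(RSS/n) + k·ln n) is selected. A structure is significantly
smaller in disease from the earliest age a\* at which the disease
band's upper bound stays below the healthy band's lower bound through
the end of the age grid (95% mean-curve bands; non-overlap of two 95%
CIs is conservative relative to a Welch test at α = 0.05, which is the
multiplicity argument). Severity is the difference of fitted means at
a reference age (90 years). Diverging structures, ordered by onset and
grouped by onset proximity and anatomical grouping (e.g.
putamen + caudate + accumbens = striatum), form the staging scheme.

A synthetic multi-cohort generator with known ground truth (healthy
polynomial, hinge onset, deviation rate, noise, TIV law per cohort)
makes every stage of the pipeline testable end to end, including
parameter-recovery studies.

## Worked example

```r
library(brainchart)

sim <- simulate_cohort(psp_cohorts(2000, 60), psp_truths(), seed = 42)
run <- stage_cohort(sim$subjects, metadata = default_structure_metadata(),
                    seed = 42)
print(run)
#> Staging run: 2060 subjects (2000 controls, 60 cases), 11 structures
#>   disease model constrained over the lifespan with 1064 records (controls < 55.5 y + cases)
#>   10 of 11 structures diverged (case smaller)
#> Staging scheme: 10 structures in 6 stages (gap threshold 2 y)
#>   stage 1 (35.5-35.5 y): brainstem (35.5 y, d=0.66)
#>   stage 2 (47.0-51.5 y): ventral_diencephalon (47.0 y, d=2.40), thalamus (49.0 y, d=4.65), pallidum (50.5 y, d=3.67), caudate (51.5 y, d=1.38)
#>   stage 3 (54.5-56.5 y): amygdala (54.5 y, d=1.28), putamen (56.5 y, d=2.50)
#>   stage 4 (64.0-64.0 y): occipital_pole (64.0 y, d=0.51)
#>   stage 5 (67.0-67.0 y): supp_motor_cortex (67.0 y, d=1.71)
#>   stage 6 (80.0-80.0 y): hippocampus (80.0 y, d=0.92)

head(rank_severity(run$divergence_table), 3)
#>   structure diverged onset_age distance_at_ref    direction
#> 1  thalamus     TRUE      49.0        4.646252 case_smaller
#> 2  pallidum     TRUE      50.5        3.673614 case_smaller
#> 3   putamen     TRUE      56.5        2.500383 case_smaller
```

Reading this: 2000 simulated controls (ages 1-100) and 60 simulated
patients (55-86) were generated from a ground truth emulating the
PSP-RS cascade. The disease models were anchored over the lifespan by
the 1004 controls younger than the youngest patient plus the 60
patients. Ten structures' disease trajectories separated from their
healthy charts (the truly spared cerebellum was not flagged;
hippocampus at 80 y is a late false positive); the timeline spans six
stages, and the severity ranking at age 90 recovers the
thalamus > pallidum > putamen ordering with distances in z-units
(`d=...` above). Fitted models are ordinary S3 objects with `print`,
`summary`, `coef`, `predict`, `confidence_band`, `residuals`,
`simulate` and `plot` methods; `write_staging_run(run, dir)` writes
models.json, divergence.csv, staging.csv/json, QC reports, report.md
and a manifest, byte-identically across reruns.

Onset ages from band non-overlap are systematically compressed
relative to ground truth (late onsets detected early); see the methods
vignette (`vignettes/brainchart-methods.Rmd`) before interpreting the
timeline quantitatively.

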