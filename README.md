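# qboldgrade

Multiparametric quantitative-BOLD MRI analysis for differentiating WHO
grade II/III glioma from grade IV glioblastoma.

Gliomas of different WHO grades overlap heavily on anatomical MRI, but
physiological imaging captures the underlying biology: perfusion (dynamic
susceptibility contrast, DSC) reflects angiogenesis, and quantitative BOLD
imaging reflects vascular deoxygenation, i.e. hypoxia. `qboldgrade`
implements the full analysis chain for grading from such multiparametric
data:

1. **Quantitative mapping** — voxelwise T2\* and T2 from multi-echo
   gradient-echo and (even-echo-restricted) spin-echo series;
   R2′ = 1/T2\* − 1/T2; relative cerebral blood volume (rCBV) as the
   time-integral of ΔR2\*(t) normalized to 1.5% in healthy white matter;
   and the relative oxygen extraction fraction

   rOEF = R2′ / (c · rCBV),  c = 4/3·π·γ·Δχ·B₀ = 317 Hz at 3 T.

2. **VOIs and features** — healthy-brain z-scoring of the anatomical
   contrasts; four tumor volumes of interest (comprehensive
   FLAIR-hyperintense tumor, contrast-enhancing tumor, solid T2-visible
   tumor, high-rOEF areas above healthy mean + 1 SD); mean/SD/min/max and
   volume per map and VOI → 116 features per subject.

3. **Classification** — an oblique random forest (logistic-regression node
   models, sparse split projections, Gini splits) with stratified 5-fold
   cross-validated ROC/AUC, and a bootstrapped significance-count feature
   importance: a feature earns +1 whenever its node-model Wald test is
   significant at 0.05 and −1 otherwise, averaged over bootstrap refits and
   z-standardized across the 116 features. Features with z > 1.96 get
   Cohen's d and Welch-t effect reports.

4. **Synthetic cohort generator** — digital phantoms (nested tissue
   ellipsoids with ground-truth T2\*, T2, blood volume and oxygen
   extraction; raw echo/DSC/anatomical volumes with Gaussian magnitude
   noise) whose between-grade effect sizes are calibrated to configurable
   Cohen's d targets, so the entire pipeline is testable end to end without
   patient data.

## Worked example

A synthetic cohort of 100 subjects (73 glioblastoma / 27 grade II/III by
the default class balance) analyzed with scaled-down settings (50 trees,
100 bootstrap iterations):

```r
library(qboldgrade)
cfg <- pipeline_config(sim = sim_config(n_subjects = 100, seed = 7),
                       n_trees = 50, n_bootstrap = 100, seed = 7)
rep <- run_pipeline(cfg)
```

Output printed by the run (your exact numbers depend only on the seed):

```
AUC: 0.96
confusion: TP=72 FP=12 TN=15 FN=1 | acc=0.870 sens=0.986 spec=0.556
features with importance z > 1.96:
                 feature    z      d        p
         t1ce__flair__sd 4.36  2.538 6.84e-21
     cbv__high_roef__min 3.16 -1.107 1.74e-03
    roef__high_roef__max 3.02  1.036 1.21e-06
        roef__flair__max 2.92  1.036 1.21e-06
          t2__flair__min 2.84  0.564 2.32e-02
         flair__t2t__min 2.58 -0.792 1.02e-03
 r2prime__high_roef__min 2.24 -1.067 1.78e-03
```

The pooled cross-validated AUC of 0.96 says the forest separates the
grades well; the sensitivity/specificity asymmetry reflects the 73/27
class balance at the 0.5 probability threshold. The importance ranking is
led by two of the planted grade signals — T1ce standard deviation in the
FLAIR-hyperintense tumor and the maximum rOEF in the high-rOEF VOI —
followed by correlated relatives of the planted signals (e.g.
`roef__flair__max` is the same peak measured in the enclosing VOI, and the
blood-volume minima echo the planted CBV heterogeneity), each reported
with its Cohen's d and two-sided Welch p-value. Which correlated relative
of a planted signal crosses the cutoff varies with the cohort draw, as it
does between real cohorts.

Subject data can also be written to and read from an on-disk NIfTI layout
(`write_cohort_nifti()` / `read_cohort_nifti()`, one directory per subject
plus `labels.csv`), which is also how real, already-coregistered data with
supplied VOI masks enters the pipeline (`pipeline_config(mode = "real")`).

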