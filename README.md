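# recistmask

Automated, rule-based tumour treatment-response assessment from 3D
segmentation masks, with the evaluation machinery such a pipeline needs.

## What problem this solves

Oncologic imaging follow-up is scored with RECIST 1.1 (Response Evaluation
Criteria in Solid Tumors): a radiologist measures the longest axial
diameters of up to five *target lesions* at baseline and follow-up and
classifies the case as complete response (CR), partial response (PR),
stable disease (SD) or progressive disease (PD). When lesions are available
as 3D masks — e.g. liver metastases segmented on diffusion-weighted MRI,
manually or by a cascaded liver→lesion network — the whole assessment can
be computed mechanically and reproducibly. `recistmask` is that program,
written for people building or evaluating automated response-assessment
pipelines: medical-image analysis researchers and quantitative-imaging
engineers.

The core computation, for a baseline/follow-up pair of (liver, tumour)
masks on a shared voxel grid:

1. **Lesion extraction** — tumour ∩ liver, 26-connected components.
2. **Measurement** — per lesion, the longest axial diameter
   `d = max_slice max_{p,q in slice} ||p − q||` over in-plane voxel centers
   (2D Feret diameter, in mm), plus volume and centroid.
3. **RECIST 1.1 rules** — lesions with `d ≥ 10 mm` are measurable; the
   `n ≤ 5` largest form the target set with sum of longest diameters
   `SLD = Σ d_i`; with `Δ% = 100·(SLD_fu − SLD_bl)/SLD_bl`:

   | rule (in order) | category |
   |---|---|
   | target count increased (new lesions) | PD |
   | `SLD_fu = 0` | CR |
   | `Δ% ≥ +20` and `SLD_fu − SLD_bl ≥ 5 mm` | PD |
   | `Δ% ≤ −30` | PR |
   | otherwise | SD |

Around the engine: segmentation metrics (Dice, volumetric similarity, set
Hausdorff distance in mm), agreement statistics (confusion matrix, exact
binomial accuracy CI, Cohen's kappa with asymptotic CI, ordinal /
one-vs-rest AUC), a synthetic phantom generator with analytic ground truth,
and a compact pure-R two-stage 3D U-Net for desk-scale experiments. See the
vignette in `vignettes/` for the methods and their assumptions.

## Worked example

Generate a longitudinal phantom whose true change is a 44% shrinkage of a
single liver metastasis, then run the full assessment:

```r
library(recistmask)

lsp <- random_longitudinal_spec("PR", seed = 42)   # known ground truth
cs  <- make_longitudinal_case(lsp)                 # rasterized masks
res <- assess_pair(cs$baseline$tumor, cs$baseline$liver,
                   cs$followup$tumor, cs$followup$liver)
print(res)
```

```
RECIST response: PR
  baseline sum: 29.1 mm over 1 target(s)
  follow-up sum: 16.2 mm over 1 target(s)
  percent change: -44.5%; new lesions: FALSE
  rule trace:
    - no new lesions 
    - change -44.5% <= -30% -> PR 
```

The baseline lesion table behind those sums:

```r
as.data.frame(extract_lesions(cs$baseline$tumor, cs$baseline$liver))
```

```
  lesion_id n_voxels volume_mm3 longest_axial_diameter_mm diameter_slice
1         1     1510      13590                  29.12473             13
```

Reading: one 29.1 mm lesion at baseline (true diameter 29.6 mm; the
≤1-voxel shortfall is the center-to-center measurement convention), 16.2 mm
at follow-up, a −44.5% change in the diameter sum (analytic truth −43.8%),
classified PR because the decrease exceeds 30% and no new lesion appeared.
The `rule_trace` records every rule consulted.

Real masks enter the same way: `read_mask("tumor.nii.gz")` reads any
NIfTI label volume (spacing from the header, slice axis inferred from the
anisotropy), and `assess_pair()` takes it from there. A thin command-line
front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "recistmask", package = "recistmask"))')" \
  assess --baseline-tumor bT.nii.gz --baseline-liver bL.nii.gz \
         --followup-tumor fT.nii.gz --followup-liver fL.nii.gz --out report.json
```

with further subcommands `lesions`, `segmetrics`, `agree`, `split` and
`phantom`.

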