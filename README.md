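# mothcolr

Assemblage-level colour diversity of moths along elevational gradients.

## The problem

Why do insect assemblages in colder environments look more alike? The
thermal melanism hypothesis predicts that low temperatures select for
darker colouration (lower brightness V, higher saturation S), because
dark ectotherms absorb heat faster. If cold restricts species to a
darker region of colour space, it should also *reduce the colour
diversity* of high-elevation assemblages. `mothcolr` provides a tested,
fully seeded pipeline for quantifying that effect from specimen
images, aimed at ecologists studying trait diversity along
environmental gradients:

- a **synthetic specimen generator** (procedural moths with
  ground-truth five-part masks: body, left/right forewing, left/right
  hindwing) with planted, tunable melanism and environmental-filtering
  effects, so every stage is testable without an image corpus;
- classical **background segmentation** (deterministic two-means
  clustering + background-consistency reclamation + contour repair)
  scored by mean intersection-over-union;
- deterministic **colour/shape feature embeddings**, cosine distances
  `d(u, v) = 1 − u·v / (‖u‖‖v‖)`, and classical (Torgerson) MDS;
- **assemblage analysis**: 100-m elevation bins, within-assemblage
  diversity = mean pairwise cosine distance, OLS trend with
  `F(1, n−2)`, pairwise and family-grouped bootstrap 95% CIs;
- **T-statistics**: per-assemblage variance ratios `T_IC/IR`
  (within-assemblage / regional individual variance; low = external
  filtering) and `T_IP/IC` (pooled within-species / within-assemblage
  variance; low = internal filtering, i.e. competition);
- **melanism indices** `B = B_f/B_w`, `S = S_f/S_w` comparing the
  resting-exposed parts (body + forewings) to the whole specimen;
- a standardized **path model** temperature → relative brightness →
  log `T_IC/IR`, and a **colour-space simulation** showing that darker
  HSV regions have lower RGB variance.

## Worked example

```r
library(mothcolr)

cfg <- paper_regime_config(seed = 1)    # 250 species, 0-2500 m,
                                        # 19 occupied 100-m bins
rep <- run_pipeline(cfg, boot_pairwise_reps = 5000, boot_family_reps = 1000)

nrow(rep$diversity$records)             # 19 assemblages
rep$diversity$trend$slope               # -3.784091e-05  (per m)
rep$diversity$trend$r2                  # 0.6134315
rep$diversity$trend$df2                 # 17
subset(rep$diversity$boot_pairwise, param == "slope")
#   param         lower        upper
#   slope -4.311421e-05 -3.27642e-05
rep$path
# Standardized path model (n = 19 assemblages)
#   temperature -> brightness    coef =  0.957  R2 = 0.916  p = 1.36e-10
#   brightness -> log T_IC/IR    coef =  0.620  R2 = 0.385  p = 0.00459
#   indirect effect (product)    =  0.594
```

Reading the output: colour-feature diversity falls by about 3.8 x 10^-5
per metre of elevation (R² = 0.61 across the 19 assemblages), and the
bootstrap interval for the slope excludes zero, so the planted
melanism/filtering structure is recovered through the full image
pipeline. The path model attributes it to the planted chain: warmer
assemblages are relatively brighter (coefficient 0.96), and brighter
assemblages hold more trait variation relative to the regional pool
(0.62).

Individual stages are exported too — `generate_dataset()`,
`cluster_segment()` / `repair_mask()` / `mean_iou()`,
`embed_specimen()`, `cosine_dist_matrix()`, `mds_project()`,
`t_stats()`, `specimen_indices()`, `fit_path()`,
`constraint_experiment()` — see the function documentation and the
methods vignette (`vignettes/colour-diversity-methods.Rmd`).

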