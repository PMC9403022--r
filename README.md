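# epistroma

Automated epithelium/stroma segmentation and quantification for
hematoxylin-and-eosin (H&E) stained histopathology, with downstream
correlation of tissue ratios against gene expression.

## The problem

The balance between tumor-cell-bearing epithelium and supportive stroma —
the tumor–stroma ratio — is a prognostic factor in breast cancer, but
extracting it from gigapixel whole-slide images (WSIs) by hand is
infeasible at cohort scale. `epistroma` implements the full automated
chain for researchers in computational pathology:

1. **ROI detection** — downsample ×16, convert to CIELAB and keep the
   chroma channels (a\*, b\*), split pixels with K-means (K = 2), label the
   cluster under the upper-left (usually unstained) pixel as background,
   and take the bounding box of the largest 8-connected foreground
   component.
2. **Tiling** — cover the ROI with non-overlapping 1128 × 720 patches;
   discard tiles with more than 80% background (exactly 80% is kept).
3. **Segmentation** — a dilated-convolution encoder–decoder network
   classifies each pixel as background / epithelium / stroma. The
   reference primitive is the dilated convolution
   `y[i] = Σ_k x[i + r·k] w[k]`, whose rate `r` widens the receptive
   field without extra parameters; the decoder applies four parallel
   dilated convolutions producing `r²·c` channels and rearranges them with
   sub-pixel (multi-channel) upsampling, summing the branches pixelwise.
4. **Stitching and quantification** — patch predictions are reassembled
   into a global tissue mask and summarised as
   `Ratio_epi = ΣE_i / ΣT_i`, `Ratio_stro = ΣS_i / ΣT_i` over valid
   patches (T = E + S, so the ratios sum to 1), plus a ten-metric
   confusion suite (TPR, TNR, PPV, NPV, FPR, FDR, FNR, ACC, F1, MCC).
5. **Genomics** — per-gene Spearman correlation of expression with both
   ratios, selection of the top 1% of genes per tissue, and hypergeometric
   over-representation analysis of GMT gene sets with Bonferroni
   adjustment.

Because real annotated cohorts are large and restricted, the package ships
synthetic generators (`generate_slide`, `generate_patch_dataset`,
`generate_expression`, `generate_annotation`) that plant known ground
truth — tissue masks, epithelial fractions, ratio-correlated gene sets —
so every stage is testable end to end on a desk. See the methods vignette
(`vignettes/epistroma-methods.Rmd`) for the model, its assumptions, and
what the synthetic results do and do not certify.

## Worked example

Train the `tiny` preset on 50 synthetic patches (about 20 s on one core),
then run the full pipeline on a synthetic slide with a planted epithelial
fraction of 0.55:

```r
library(epistroma)

ds  <- generate_patch_dataset(50, 96, 96, c(0.2, 0.8),
                              background_prob = 0.4, seed = 1)
fit <- train_model(build_model(model_config("tiny", seed = 1)), ds,
                   train_config(seed = 1))
tail(fit$history, 2)
#>   epoch       loss  accuracy
#> 5     5 0.06712708 0.9759744
#> 6     6 0.04646839 0.9825152

slide <- generate_slide(slide_spec(1128, 720, epi_fraction_target = 0.55,
                                   seed = 42))
res <- process_slide(slide$image, fit$model, patch_w = 376, patch_h = 240,
                     factor = 16, seed = 1)
res$roi
#> ROI rows [64, 640), cols [112, 1008)
res$grid
#> patch grid 376 x 240 px: 9 tiles, 6 retained
compute_ratios(count_patch(res$mask))
#> epithelial ratio 0.5540, stromal ratio 0.4460
```

The training history shows per-epoch mean cross-entropy and training
pixel accuracy; the detected ROI brackets the planted ellipse; and the
estimated epithelial ratio (0.554) recovers the planted fraction (0.550)
to half a percentage point. `background_prob = 0.4` exposes the network
to background bands during training, which it needs before meeting slide
background at inference time.

For the genomics arm, `generate_expression` plants genes that track a
ratio at a target Spearman correlation, `correlate_expression` +
`select_top_fraction` recover them, and `ora_enrich` + `top_terms` rank a
planted annotation term first — see `tests/testthat/test-genomics.R` for
complete runnable chains.

A command-line front end (`exec/epistroma`) wraps the same functions:
`synth-slide`, `synth-patches`, `synth-expression`, `synth-gmt`, `train`,
`segment`, `quantify`, `correlate`, each with `--seed`.

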