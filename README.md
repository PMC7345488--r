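# tearllt

Quantifies tear-film **lipid layer thickness (LLT)** — a film of a few tens
of nanometers whose thinning drives evaporative dry eye — from the
interference colors visible in the bright rings of a placido-disk tear film
analyzer (Keratograph 5M-style imagery). It is aimed at ophthalmic imaging
researchers who want a standardized, scriptable LLT readout from blink-cycle
recordings without a dedicated interferometer.

## Method

One qualified opening blink cycle (duration strictly > 2 s, inferior ring
reflection always visible) is decomposed from eye opening (t = 0) to 2 s at
0.05-s intervals (41 frames). Per frame:

1. **Pre-segmentation ROI**: the inferior half of the corneal annulus,
   excluding the area inside the central 2 placido rings.
2. **Post-segmentation ROI**: bright interference-ring pixels, isolated by
   the Kapur maximum-entropy threshold *t\** of the ROI luminance
   histogram — *t\** maximizes `H_bg(t) + H_fg(t)`, the summed Shannon
   entropies of the background/foreground histogram partitions. The dark
   ring background and dark occluders (eyelashes) are removed together.
3. **Color inversion**: each ROI pixel `(r_i, g_i, b_i)` takes the LLT of
   the look-up table reference point `(R_j, G_j, B_j)` minimizing

   `√((r_i − R_j)² + (g_i − G_j)² + (b_i − B_j)²)`

   and the frame's LLT is the ROI mean (Σ LLT / pixel count).
4. **Pre-to-post transform**: the dark background biases the unsegmented
   average, so a per-timepoint linear model predicts the post-segmentation
   LLT from the pre-segmentation LLT: `0.65·pre + 8.73` at 0.5 s,
   `0.58·pre + 11.27` at 1.0 s, `0.55·pre + 11.01` at 2.0 s (simplified
   common rule `0.6·pre + 10`); `fit_transform()` re-estimates coefficients
   from paired data.

The look-up table itself is regenerated from two-interface thin-film optics
(Airy reflectance of an n = 1.48 film on n = 1.336 aqueous, CIE 1931 2°
colorimetry, white-balanced 8-bit sRGB); a measured instrument table can be
substituted via `read_lookup_table()`. Reliability is assessed with
ICC(2,1), Pearson correlation and paired t-tests. A phantom generator
renders placido-ring interference images with known ground-truth LLT fields
for end-to-end validation.

## Worked example

```r
library(tearllt)
tab <- build_lookup_table(optics_config())
ph <- render_phantom(
  phantom_spec(llt_field = list(profile = "uniform", value = 60),
               noise_sd = 3, seed = 1), tab)
cyc <- blink_cycle(lapply(seq(0, 2, 0.05), function(t)
  tear_frame(t, ph$image)))
run_estimate(list(input = cyc, table = tab, subject_id = "phantom-60nm"))
#>     subject_id t_s stage mean_llt_nm pixel_count transform_source transformed_llt_nm
#> 1 phantom-60nm 0.5   pre    32.61013       19968      paper-fixed           29.92658
#> 2 phantom-60nm 1.0   pre    32.61013       19968      paper-fixed           30.18387
#> 3 phantom-60nm 2.0   pre    32.61013       19968      paper-fixed           28.94557
#> 4 phantom-60nm 0.5  post    58.36930        9334             <NA>                 NA
#> 5 phantom-60nm 1.0  post    58.36930        9334             <NA>                 NA
#> 6 phantom-60nm 2.0  post    58.36930        9334             <NA>                 NA
```

The phantom's true LLT is 60 nm. The post-segmentation mean (58.4 nm, from
9334 bright-ring pixels under channel noise sd 3) recovers it to within
2 nm; the pre-segmentation mean (32.6 nm over 19968 pixels) is pulled down
by the dark ring background — exactly the bias the segmentation removes and
the transform column models. On a real instrument, whose dark background
maps to a different part of the color curve, the sign of that bias can
differ; the transform coefficients are instrument- and timepoint-specific.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/tearllt.R build-lut --out lut.csv
Rscript inst/cli/tearllt.R simulate --llt-nm 60 --output-dir scratch/run
Rscript inst/cli/tearllt.R estimate --input scratch/run/frames --lut lut.csv
```

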