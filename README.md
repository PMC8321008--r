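# mealscan

Automatic detection and counting of food-intake actions from **top-view
depth video**.

A depth sensor on the ceiling (Kinect-v1 class: 640x480 depth frames in mm
at 30 fps) watches a dining table from above. Because only distances are
recorded and the face is never imaged, the set-up suits long-term,
privacy-preserving dietary monitoring of older adults — the question it
answers is *when did the person sit down to eat, and how many bites/drinks
did they take?*

The pipeline:

1. **Preprocessing** — invalid-pixel ("hole") filling, background
   subtraction against a person-free reference frame, 5x5 median denoising,
   Sobel edges; the person's silhouette becomes a 3-D point cloud through
   pinhole intrinsics.
2. **Meal segmentation** — a per-frame checklist finds the start frame (SF:
   first frame the subject sits at the table with a hand on it) and end
   frame (EF: the subject rises, or the file ends). Sitting is decided by
   the **Ratio** test on the head-to-sensor distance: with Ratio = 0.3, a
   seated distance of 1700 mm sets the standing threshold at
   1700 x (1 - 0.3) = 1190 mm against a running standing baseline. Hands on
   the table are foreground blobs (> 300 px) within a 200 mm height band
   above the table top. Results accumulate in the 3xN **SetParam** table
   (test number, SF, EF); a meal interrupted by a short departure
   contributes several columns.
3. **Skeleton tracking** — a 50-node self-organizing-map body model (9-node
   head ring around the head joint Jhd, a torso lattice, two arm chains
   ending in the hand joints Jhl/Jhr) is fitted to each frame's point cloud
   by damped batch Kohonen rounds. A hand joint dwelling within 200 mm
   (≈ 300 px) of the head for more than 5 s (150 frames) signals *joint
   fusion* and triggers a model reset that restores separated joints.
4. **Intake counting** — one action per maximal run of head-hand distance
   below 200 mm lasting at least the dwell window (5 s by default);
   overlapping left/right runs merge, brief gaps are bridged.
5. **Evaluation** — AE = |x̂ − x|, MAE = (1/n)Σ|x̂ − x| and
   MRE% = (100/n)Σ|x̂ − x|/x score SF/EF estimates and action counts
   against ground-truth annotations.

A seeded synthetic scene generator renders top-view depth sequences of a
scripted meal (enter → sit → hands on table → hand-to-mouth actions → rise →
leave) with exact ground truth, so the whole pipeline is testable without
sensor hardware. The methods vignette
(`vignettes/mealscan-methods.Rmd`) documents the model, the parameters and
their defaults, and the generator's scope.

## Worked example

```r
library(mealscan)

script <- meal_scene_script(n_frames = 700, n_actions = 4, seed = 42)
scene  <- render_sequence(script)          # frames + ground truth

res <- evaluate_session(scene$frames, scene$background,
                        cfg     = scene_session_config(script),
                        tparams = scene_tracker_params(script),
                        aparams = scene_action_params(script),
                        test_number = 1L)
res
#> meal evaluation: 1 segment(s)
#>  test_number sf  ef actions
#>            1 65 646       4

res$events[[1]]
#>   start_frame end_frame  hand min_distance_mm
#> 1         109       207 right        114.5186
#> 2         259       357  left        112.3319
#> 3         399       497 right        113.0441
#> 4         555       646  left        110.3080
```

The detected meal runs from frame 65 to 646 (the script seats the person
with hands on the table at frame 65 and stands them up at 645) and all four
scripted hand-to-mouth gestures are recovered, each with its hand label and
the closest head-hand approach in mm.

Scoring the packaged 33-test campaign (automatic and manual SF/EF and
detected action counts against ground truth):

```r
evaluate_fixtures()
#>  metric    mae mre_percent  n
#>     SFA 10.636      5.537% 33
#>     EFA  1.939      0.059% 33
#>     SFM  8.939     54.410% 33
#>     EFM  7.485      0.291% 33
#>     ACT  0.424      5.044% 33
```

A thin command-line front end (`exec/mealscan`) exposes the same stages as
`simulate`, `detect`, `track`, `count` and `evaluate` subcommands over the
package's file formats (16-bit TIFF depth stacks with a YAML sidecar,
CSV SetParam tables and annotations).

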