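# taadmorph

Post-segmentation analysis of **type A aortic dissection (TAAD)** from
multi-label CT segmentations, for researchers evaluating automatic
segmenters of the dissected aorta and quantifying its morphology.

A dissection separates the aortic wall into a **true lumen (TL)** and a
**false lumen (FL)**, divided by the detached **intimal flap**. Clinical
annotations and deep-learning segmenters typically label only TL and FL;
the flap and all morphometry must be recovered afterwards. `taadmorph`
implements that post-processing chain:

* **Label-volume I/O** — NIfTI-1 label volumes (`0` background, `1` TL,
  `2` FL, `3` flap after extraction) with physical voxel spacing,
  including float-stored labels and foreign-label remapping.
* **Flap extraction** — per slice, a curvature-regularised morphological
  contour evolution over the merged TL + FL region yields the whole-aorta
  mask; the flap is the remainder after removing the two lumens, so that
  aorta = TL ⊔ FL ⊔ flap exactly.
* **Morphometry** — maximum Feret diameters of aorta, TL and FL; lumen
  areas; mean flap thickness by a sub-pixel medial-axis width estimator;
  per-patient averages and per-patient-first relative errors.
* **Segmentation evaluation** — per-voxel, per-label
  accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
  recall = TP/(TP+FN), IoU = TP/(TP+FP+FN), DSC = 2TP/(2TP+FP+FN), and
  the exact symmetric Hausdorff distance
  HD = max(h(G,P), h(P,G)), h(A,B) = max<sub>a∈A</sub> min<sub>b∈B</sub> ‖a−b‖₂
  in mm over full voxel-centre sets (distance-transform based);
  cross-validation fold assignment; Shapiro–Wilk + paired t-test for
  comparing two segmenters.
* **Phantom generator** — synthetic dissected-aorta volumes (disc cross
  section split by a chord band) with closed-form ground-truth
  morphometry, plus controllable degraded "predictions", so the whole
  chain is testable without patient data.
* **Pipeline** — `run_pipeline()` chains simulate → evaluate → quantify,
  writes CSV tables, NIfTI volumes and watertight STL surface meshes, and
  logs every skipped slice/patient;
  `inst/cli/taadmorph.R` is a thin command-line front end.

## Worked example

```r
library(taadmorph)

# a 50 mm dissected-aorta phantom: 2.4 mm flap, 6 mm chord offset
spec <- phantom_spec(outer_diameter = 50, flap_thickness = 2.4,
                     flap_offset = 6, n_slices = 12, seed = 1)
phantom <- generate_phantom(spec)
phantom$truth
#>   aortic_diameter tl_diameter fl_diameter  tl_area  fl_area flap_thickness
#> 1              50    47.88152          50 626.7882 1220.265            2.4

# a degraded "prediction" and its six-metric evaluation
pred <- degrade_prediction(phantom$annotation,
                           degradation_spec(boundary_shift_mm = 0.9,
                                            flip_fraction = 0.05, seed = 1))
patient_metrics(phantom$annotation, pred)
#>   label accuracy precision recall    iou    dsc    hd
#> 1    TL   0.9976    0.9815 0.9946 0.9763 0.9880 32.10
#> 2    FL   0.9974    0.9905 0.9962 0.9868 0.9933 19.93

# recover the intimal flap and quantify morphology
flapped <- extract_flap_volume(phantom$annotation)
patient_morphometry(flapped, patient_id = "phantom01")
#>   patient_id n_slices_used aortic_diameter tl_diameter fl_diameter tl_area
#> 1  phantom01            12           49.85       47.05       49.83   624.3
#>   fl_area flap_thickness
#> 1    1217          2.252
```

Ratio metrics are fractions in [0, 1] (tables report %); `hd` is in mm.
The boundary degradation of ~1 px keeps overlap metrics near 1, while a
few TL↔FL swaps on the lumen rims dominate the Hausdorff distances — it
is a max-type metric and single misplaced voxels move it by centimetres.
The recovered morphometry sits within one in-plane pixel (0.8242 mm) of
the analytic truth for diameters and thickness and within a few mm² for
areas.

## Vignette

`vignettes/dissection-morphometry.Rmd` documents the model and the
design decisions: the contour-evolution engine, the Feret-diameter and
medial-axis thickness definitions, undefined-metric handling, Hausdorff
units, what the phantom does and does not emulate, and known
limitations.
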