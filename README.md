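# birdparts

Part-based fine-grained bird species recognition in R: an attention-augmented
single-stage detector finds four bird parts (head, left wing, right wing,
tail) labelled jointly with the species, and a weighted confidence vote over
the detected parts decides the species of the image.

The package is for researchers working on fine-grained visual categorization
— problems where within-class variation (pose, lighting) dwarfs
between-class variation, and the discriminative evidence sits in small
semantic parts. It implements the complete pipeline at desk scale: PASCAL
VOC part-annotation I/O, box-consistent augmentation, the detector with its
attention blocks (forward *and* backward passes are hand-implemented on
RcppArmadillo, so everything runs on a plain CPU without a deep-learning
runtime), detection metrics, the part-table reduction, the exhaustive
part-weight search, and a synthetic scene/table generator that makes the
whole pipeline trainable and testable without any external dataset.

## The model

**Label space.** With `S` species and 4 parts, detection classes are
`class_id = (species_id − 1) · 4 + part`, giving `4S` part-species classes
(800 at `S = 200`).

**Detector.** A 32-layer single-stage graph: backbone Conv/C3 stages, a
Res2Net-CBAM residual unit after every backbone C3, SPPF, an FPN+PAN neck
with a CBAM block at each output scale, and a 3-anchor detection head at
strides 8/16/32 emitting `4S + 5` values per anchor. The attention blocks:

* channel attention `Mc(F) = σ(W₁ relu(W₀ avg(F)) + W₁ relu(W₀ max(F)))`,
* spatial attention `Ms(F) = σ(f⁷ˣ⁷[mean_c(F); max_c(F)])`,
* CBAM: `F' = Mc(F) ⊗ F`, output `Ms(F') ⊗ F'`,
* Res2Net-CBAM: entry 1×1 conv, channel split into `s` groups with the
  hierarchical chain `Y₁ = X₁`, `Y₂ = K₂(X₂)`, `Yᵢ = Kᵢ(Xᵢ + Yᵢ₋₁)`,
  concat, exit 1×1 conv, CBAM, plus a residual connection from the block
  input.

**Fusion.** Per image, keep the highest-confidence detection of each part
(≤ 4 records). For a weight vector `w` on the simplex, each record votes
`w[part] · confidence` for its species; the argmax wins (ties to the lower
species id). All weight vectors in hundredths summing to 1 — `C(103,3) =
176,851` of them at the 0.01 grid — are evaluated exhaustively, and the
accuracy maximiser on a labelled validation split is reported.

**Metrics.** Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, all-point
interpolated AP per class, mAP@0.5 (IoU 0.5 as the TP criterion), and
classification accuracy.

## Worked example

The fusion stage on a synthetic validation table with planted per-part
informativeness (head records correct with probability 0.95, wings 0.5,
tail 0.3; confidences Beta(8,2) when correct, Beta(2,4) when wrong):

```r
library(birdparts)

tab <- generate_detection_table(1000, n_species = 200, seed = 42)
fit <- grid_search_weights(tab$records, tab$truth, step_hundredths = 1L)
fit
#> Part-weight grid search (step 0.01)
#>   evaluated : 176851 weight vectors
#>   best      : head 0.29, leftwing 0.27, rightwing 0.22, tail 0.22
#>   accuracy  : 0.9670  (2 tied maximisers, 0 abstentions)
```

All 176,851 grid vectors are evaluated; the best vector classifies 96.7% of
the 1,000 images correctly. The optimal weights are flatter than the
per-part correctness rates because with 200 species two wrong records
almost never agree, so cross-part agreement is itself strong evidence —
head-only weighting reaches just 85.9% on the same table:

```r
acc <- classification_accuracy(
  predict_species(tab$records, c(100, 0, 0, 0),
                  image_ids = tab$truth$image_id),
  tab$truth)
acc
#> [1] 0.859
```

End to end on synthetic scenes (schematic birds whose coloured part glyphs
encode the species):

```r
scenes  <- generate_scenes(64, n_species = 8, canvas_size = 160, seed = 101)
holdout <- generate_scenes(32, n_species = 8, canvas_size = 160, seed = 202,
                           id_prefix = "held")
cfg <- detector_config(num_classes = 32, width_multiple = 0.125,
                       depth_multiple = 0.25, input_size = 160)
fit <- train_detector(scenes, cfg, epochs = 50, lr = 0.02, seed = 1)
det <- detect_images(fit, holdout$images, conf_threshold = 0.001)
evaluate_detections(det, holdout$annotations)$map50   # ~0.7 on held-out scenes
```

(Training is ~5 minutes on one CPU core at this profile.) The layer graph
itself can be audited against its documented shape table at full
multipliers — `audit_shapes(build_network(detector_config()))` runs a
640×640 forward pass and checks all 34 recorded shapes, ending in the
20×20×1280 SPPF output and the 805-per-anchor head.

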