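# myelinGT

Ground-truth extraction and annotator evaluation for myelin in
multi-channel fluorescence z-stacks.

## The problem

Myelin is a sheet of oligodendrocyte membrane wrapped around a neuronal
axon. In multi-spectral fluorescent images it can only be identified as
*co-localization*: pixels bright in both the oligodendrocyte channel
(e.g. anti-MBP) and the axon channel (e.g. anti-TUJ1), within shape and
size criteria that live in the expert's eye. Staining is granular, so
the apparent continuity of a myelin segment has to be judged by a human;
machine-learning segmenters need large amounts of such expert-annotated
ground truth, and producing it pixel by pixel is the bottleneck.

`myelinGT` is a headless, scriptable implementation of the full
ground-truth workflow for R:

1. **Candidate detection** — per z-section, binarize the three channels
   (per-section Otsu or fixed thresholds), remove *cell bodies*
   (the dilated overlap of the nucleus mask with the cellular-marker
   mask), and intersect the remaining oligodendrocyte signal with the
   axon signal:

   `candidates = (O \ dilate(N ∧ O)) ∧ A`,

   followed by an 8-connected minimum-component-area filter. Candidates
   are a superset of true myelin that annotators then adjudicate.
2. **Vector annotation** — expert markings are polylines with an odd
   pixel thickness (Bresenham path + centred disk), serialized to an
   open JSON format; binary masks convert to vectors (skeletonization,
   junction splitting, distance-transform thickness estimation) and
   back, and conversion *overwrites* existing vectors.
3. **Adjudication** — two annotators' sets are merged side by side,
   edited (delete / trim / draw), and an adjudicated set is rasterized
   into the gold-standard mask TIFF.
4. **Evaluation** — annotators are scored by pixel precision,
   `precision = 100 · TP / (TP + FP)`, optionally restricted to the
   candidate-pixel domain; per-annotator averages are pooled into an
   overall mean of annotator means.
5. **Synthetic data** — a seeded generator of wriggling, granular,
   co-localized fiber stacks with known ground truth, so the entire
   pipeline is testable without microscope data.

## Worked example

```r
library(myelinGT)

# a 256 x 256 x 3 synthetic stack with 12 fibers and known gold standard
gen  <- generate_stack(synth_config(seed = 1))
cand <- detect_candidates(gen$stack, detection_config("otsu"))
candidate_pixel_count(cand)   # 1453
positive_count(gen$gold)      # 2014

# two simulated annotators with planted error rates
e1 <- corrupt_annotation(gen$gold_vectors, fp_rate = 0.25, fn_rate = 0.1,
                         seed = 2, source = "expert1")
e2 <- corrupt_annotation(gen$gold_vectors, fp_rate = 0.10, fn_rate = 0.3,
                         seed = 3, source = "expert2")

# adjudicated truth -> gold masks -> per-annotator precision report
gold   <- extract_gold_standard(list(e1, e2), gen$gold_vectors)
report <- build_report(lapply(list(e1, e2), function(s)
  list(image_id = "demo", annotator_id = s$source,
       counts = confusion_counts(rasterize_all(s), gold))))
print(report)
#>  image_id annotator_id   tp  fp  fn precision_percent
#>      demo      expert1 1932 667  82             74.34
#>      demo      expert2 1122 148 892             88.35
#> overall average precision (paper-style, mean of annotator means): 81.34%
```

The candidate count is below the gold count because staining granularity
(15% independent pixel dropout per channel) breaks co-localization at
roughly `1 - 0.85² ≈ 28%` of fiber pixels — exactly the gap a human
annotator bridges. The recovered precisions sit at the planted
false-positive rates (75% and 90%) up to stroke granularity.

A command-line front end wraps the same functions:

```sh
myelin-gt synth --out-dir fixtures/
myelin-gt detect --oligo fixtures/oligodendrocyte.tif --axon fixtures/axon.tif \
    --nucleus fixtures/nucleus.tif --out candidates.tif
myelin-gt vectorize --mask candidates.tif --out candidates.iev.json
myelin-gt evaluate --pred expert1.iev.json --gold fixtures/gold.tif --out report.csv
myelin-gt run --project project.json   # full detect -> ... -> evaluate pipeline
```

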