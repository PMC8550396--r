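---
title: "Color labeling of orchid flowers and labella: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color labeling of orchid flowers and labella: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchidcolor)
```

## The problem

Taxonomic descriptions of orchids record the color of the *flower* (the
sepals and petals taken together, CF) and of the *labellum* (the modified
lip petal, CL) as a primary color — the color filling most of the region —
plus an optional secondary color, often just a rim. `orchidcolor`
implements a segmentation-free pipeline that predicts such color labels
directly from whole photographs: no manual or automatic isolation of the
flower from its background is required. The pipeline has four parts: a
label-space algebra, CNN classifiers, label-fusion strategies, and an
evaluation toolkit, plus a synthetic image generator that makes every stage
testable end to end on a desktop machine.

## The label space

Color labels are defined over a 9 × 13 reference matrix of RGB cells
(`color_matrix()`): hue sweeps across the columns from red through yellow,
green, blue and purple; the rows run from dark saturated shades at the top
to pale tints at the bottom, with pure white in cell (9, 13). Blue
(columns 7–9) does not occur in orchid flowers or labella and is excluded
throughout — any request involving blue raises an error rather than being
silently dropped.

Two partitions of the remaining 90 cells are supported
(`color_scheme(scheme_id, target)`):

* **Scheme 1** — 4 colors. Red: columns 1–2; Yellow: column 3; Green:
  columns 4–6; Purple: columns 10–13.
* **Scheme 2** — 5 colors. Red: column 1 plus the four darkest cells of
  column 2; Yellow: the rest of columns 2–3; Green: columns 4–6; Purple:
  columns 10–13; White: the single cell (9, 13).

Two cell assignments are design decisions of this package. First, the
reference description places cell (9, 13) in no scheme-1 color but notes
that the pale end of the Yellow column is close to white; we map it to
Yellow (and flag it in the scheme definition vocabulary by documenting it
here). Second, rows 1–8 of column 13 are assigned to Purple in both
schemes: they sit on the purple-to-white edge of the hue sweep, and the
partition invariant — every non-blue cell carries exactly one label — would
otherwise be violated.

The exact per-cell RGB values carry no label semantics beyond this
partition, so the default palette is generated procedurally (hue by column,
value and saturation by row) and can be overridden cell by cell from a YAML
file (`read_palette()`). Brightness changes move a color within its column,
never across a column boundary, which keeps the labels stable under
illumination changes.

### Combinations and exclusions

A combination of a primary and a secondary color is treated as
*commutative*: `AB = BA`, and `AA` is just `A` (the flower has no secondary
color). The number of combinations of `k = 2` colors with repetition from
`n` is therefore the multichoose number `choose(n + k - 1, k)`
(`count_multichoose()`): 10 for scheme 1 and 15 for scheme 2. Canonical
names concatenate the two color names alphabetically (`canonicalize()`), a
deterministic spelling; only the equivalence `AB = BA` is fixed by the
method, not the spelling.

Combinations that do not occur in nature are excluded per target:
for scheme 1, RedPurple and GreenPurple (both CF and CL); for scheme 2,
CL additionally excludes pure Red, RedWhite and YellowGreen (5 exclusions)
and CF excludes RedPurple, RedWhite, YellowWhite and GreenPurple (4).
This yields label spaces of size 8 (CF1, CL1), 11 (CF2) and 10 (CL2):

```r
length(scheme_labels(color_scheme(2, "CF"), use_secondary = TRUE))  # 11
```

### The non-commutative ablation space

`scheme_labels(..., commutative = FALSE)` switches to the ordered label
space used to measure what commutativity buys: `AB` and `BA` become
distinct labels. The documented ablation sizes are 12/15/12/16 for
CF1/CF2/CL1/CL2. Doubling each scheme's surviving unordered pairs gives
12/17/12/16 — the CF2 value is not derivable from its own commutative
label space. We therefore configure the ablation exclusion lists as scheme
data, and for CF2 additionally drop the two orderings with White as the
*secondary* color (GreenWhite, PurpleWhite), the only reading we found
that reaches 15; White rarely appears as a mere rim on a whole flower.
The flag only changes label-space plumbing; the synthetic generator
produces canonical (commutative) labels.

## Classifiers

`color_classifier()` is the package's model-fitting function; it returns a
classed object with `print`, `summary`, `predict` and `plot` (training
history) methods. `build_classifier()` and `train_classifier()` expose the
two stages separately.

A classifier is a backbone feature extractor plus a fresh head: flatten →
dense(512, ReLU) → dropout(0.5) → dense(*m*) with softmax (multi-class) or
a single sigmoid unit (binary one-vs-rest head). Freezing
(`freeze_scheme()`) fixes the bottom ¾, ½ or ¼ of the backbone layers, only
the first layer, none, or all of them; frozen parameters are bit-identical
before and after training. Layers are counted over the backbone's layer
list (convolutions, activations and pooling each count as one layer), a
convention that differs from some depth tables which count only
parameterized layers; the freeze fraction is applied to this list.

The shipped backbones, `tinycnn` (two conv/pool blocks, 32 × 32 input) and
`smallcnn` (three blocks, 64 × 64), are small from-scratch networks for
CPU-scale work; `register_backbone()` attaches externally supplied feature
extractors. The training engine (mini-batch Adam, weighted cross entropy,
im2col convolutions over BLAS) is implemented in base R, with one global
seed governing weight initialization, shuffling, augmentation, replication
order and dropout, so runs are exactly reproducible.

Defaults in `train_config()` follow the transfer-learning setup of the
study this package operationalizes: Adam, initial learning rate 5e-5, 100
epochs, batch size 64, 224 × 224 inputs, and rotation/shrink/flip/zoom
augmentation on the training split only. Two loss conventions are
reconciled as follows: multi-class softmax heads use class-weighted
categorical cross entropy, binary heads use weighted binary cross entropy —
per-class binary cross entropy under a softmax output would be
inconsistent. Class imbalance is handled by default with replication
oversampling (`oversample_by_replication()`, cyclic and deterministic,
replicating each minority class to the majority size); an
inverse-frequency loss-weight mode is available as `balance =
"class_weight"`. Augmentation magnitudes are not fixed by the method
description; we default to ±30° rotation, 0.8–1.2 zoom/shrink and
horizontal flips, all configurable.

Desk-scale runs (the test suite and the worked examples) use the
from-scratch `tinycnn` at 32 × 32 with learning rate 1e-3 and 5–6 epochs —
a from-scratch network at this input size neither needs nor benefits from
the pretrained-backbone defaults. These problem sizes (up to 500 images
per class) are the package's own choice of a configuration that
demonstrates the pipeline's behavior reliably on a single CPU.

## Fusion strategies

Four ways of turning classifier outputs into one label:

1. **Multi-class argmax** (`predict_multiclass()`): the label with maximal
   softmax probability.
2. **One-vs-rest logical merge, method 1** (`merge_one_vs_rest()`): *m* − 1
   binary classifiers are merged logically. One positive decision names
   the label; two or more are contradictory and yield the `INCONSISTENT`
   sentinel; zero positives imply the remaining *m*-th label through the
   *domain closure axiom* (the true label is one of the *m* allowed ones)
   plus mutual exclusiveness. Binary heads are sigmoid units thresholded
   at 0.5.
3. **Max probability, method 2** (`merge_max_probability()`): the label
   whose binary head reports the highest probability; never inconsistent.
4. **Ensembles** of C1 = the multi-class classifier and C2 = the method-2
   combined-binary classifier. On agreement both return the common label.
   On disagreement, **MLTC** (`ensemble_mltc()`) picks the candidate whose
   own classifier has the higher true positive rate for it. **MLCR**
   (`ensemble_mlcr()`) computes, for each candidate, the ratio of the
   predicting classifier's TPR over the *other* classifier's TPR for the
   same label, and picks the label with the *lower* ratio — the label on
   which the two classifiers' rates are wider apart. The method's
   narrative also describes the ratio rule with the word "highest", but
   its worked example (ratios 0.66 for red vs 0.84 for white, choosing
   red) fixes the arithmetic; we implement the example.

TPR tables (`compute_tpr_table()`) are per-class recall — the diagonal of
the row-normalized confusion matrix. For ensembles they are computed on
the **validation** split: using the test split would leak evaluation data
into the decision rule.

Tie-breaking is deterministic everywhere: argmax ties take the first label
in label-space order, MLTC ties go to C1, and MLCR with exactly equal
ratios falls back to MLTC (so with identical TPR tables MLCR reduces to
MLTC's choice). A zero TPR denominator makes MLCR fall back to MLTC with a
warning.

## Metrics

`confusion()` builds raw and row-normalized confusion matrices; an
`INCONSISTENT` prediction becomes an extra predicted-only column. Overall
accuracy is the trace over the total (the binary formula
`(TP+TN)/(TP+FP+TN+FN)` generalized). `f1_per_class()` / `macro_f1()`
implement recall, precision, F1 and their unweighted macro mean; degenerate
classes with no true and no predicted instances are dropped from the macro
mean, classes with true instances but no correct or predicted ones score 0
(the standard convention; the method description is silent).
`accuracy_with_without_inconsistent()` reports the two accuracies of the
one-vs-rest merge — counting inconsistent outputs as errors, or dropping
those cases — and `set_membership_accuracy()` counts a prediction as
correct when it lies in a per-image set of acceptable labels (used when
species are known under several alternative colors). ROC analysis is out
of scope: the problems here are multi-class.

## The synthetic generator

`generate_dataset()` renders orchid-like scenes: background clutter
(textured patches and distractor blobs deliberately including green
foliage tones, so a classifier must localize the flower), a flower of 5–6
overlapping elliptical lobes, and a smaller offset labellum lobe. Each
region is filled with a per-pixel mixture of a few reference-matrix cells
of its primary label (petals are not one flat RGB) under mild shading; a
distinct secondary color occupies an outer rim of 15–35% of the region.
Illumination jitter is applied as a gamma-style brightness transform —
a multiplicative factor would clip bright channels and wash pale colors
into white, changing the label — followed by Gaussian pixel noise.
Splits are stratified 70/20/10 per class; `n_per_class` accepts a named
vector to emulate class imbalance (majority:minority ratios up to 13 occur
in the real data). Everything is deterministic under the configuration
seed.

Defaults: 224 × 224 images (tests use 32 × 32), 100 images per class, 50%
secondary-color incidence, labellum at 0.3 of the flower scale, clutter
level 0.5, illumination factors 0.75–1.25 and noise sd 0.02 — values chosen
once as a plausible cartoon of field photographs.

`pixel_vote()` is the recoverability oracle: the majority label over a
region's pixels, each mapped to its nearest reference cell by RGB
*direction* (`classify_pixels(metric = "angular")`, insensitive to
multiplicative illumination). On clutter-free samples this recovers the
generated primary label on ≥ 99% of images, guaranteeing the labels are
learnable in principle. The residual ≤ 1% sits almost entirely on the
scheme-2 Red/Yellow boundary inside matrix column 2, where adjacent cells
of different labels are genuinely close.

What the generator does *not* emulate — and hence what passing tests do not
show about real photographs: morphological variation between species,
multiple flowers per image, out-of-focus and occluded flowers, seed pods
and buds, specular highlights, and label noise in the source descriptions.
Accuracies on synthetic data characterize the pipeline, not field
performance.

## Experiments

`run_experiment()` ties the stages together from an
`experiment_config()` (or a YAML file via `read_experiment_config()`): it
derives the label space from (scheme, target, use_secondary,
commutativity), obtains a dataset (supplied, read from a manifest with
per-row label validation, or generated), trains the classifier(s) the
requested fusion strategy needs, computes validation TPR tables for
ensembles, and evaluates on the test split. Reports include accuracy,
macro-F1, the confusion matrix, both accuracy variants for method 1, and
the base-classifier disagreement count for ensembles. A thin command-line
front end is installed under `inst/cli/orchidcolor`.

## Known limitations

* No pretrained ImageNet backbones ship with the package (they require a
  network download); the freeze machinery is exercised on the small
  built-in backbones and accepts registered external ones.
* The base-R training engine is adequate for the built-in backbones at
  32–64 pixel inputs; it is not a general-purpose deep-learning framework.
* The non-commutative CF2 ablation space is a configured reading (see
  above), not a derivation.
* Synthetic results quantify pipeline correctness, not real-world
  accuracy.
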