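---
title: "Grading facial paralysis from corresponded 3D face meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading facial paralysis from corresponded 3D face meshes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Unilateral facial paralysis weakens voluntary movement on one side of the
face. Clinically it is graded by experts watching a patient perform a set of
voluntary expressions and scoring each on an ordinal scale (here a modified
Sunnybrook scale: three resting-symmetry parameters and five
voluntary-movement parameters graded 1 = no movement to 5 = normal). Expert
grading is the accepted standard but suffers from limited intra- and
inter-observer reproducibility. `palsy3d` implements an objective
alternative: dynamic 3D surface captures of the face at rest and at the peak
of each expression are converted into corresponded point-cloud pairs and
regressed against the expert consensus grade by a dual-branch PointNet.

The package assumes the upstream capture chain (stereo reconstruction,
temporal tracking, conformation of a generic mesh to the scan) has already
produced *corresponded* triangle meshes: every mesh of a cohort has the same
vertex count and ordering as the reference template, so vertex `i` is the
same anatomical point on every face. That correspondence, not the
triangulation, is what every stage below consumes.

## Geometry

**Alignment.** The rest-frame face is superimposed on the symmetric template
by *partial Procrustes* superimposition: the rotation + translation (no
scaling, no reflection) minimizing the sum of squared corresponded
distances, solved in closed form from the SVD of the 3×3 cross-covariance
with the determinant-corrected Kabsch construction. Scaling is deliberately
excluded — severity information lives in millimetre-scale movement
amplitudes, which a similarity fit would renormalize away. The peak frame is
then aligned to the aligned rest frame using only three landmarks (both
inner eye corners and the nose tip), which are nearly motionless across
expressions; this removes head motion between the frames without absorbing
the expression deformation itself. Configurations whose cross-covariance has
rank < 2 (collinear or coincident points) leave the rotation undetermined
and are rejected; coplanar configurations — which include every 3-landmark
fit — are well-posed under the det = +1 constraint and accepted.

**Asymmetry.** The mirror of a mesh reflects the coordinates about the
template's sagittal plane (x = 0) and re-indexes the vertices through the
template's left–right pairing, so the mirror is itself in correspondence.
The asymmetry field aligns the mirror back onto the original by partial
Procrustes and takes per-vertex point-to-point distances. The field of a
perfectly symmetric face is identically zero, and `value(i) = value(pair(i))`
holds because left and right differ by the same absolute amount. Distances
are point-to-point between corresponding vertices (not point-to-surface):
correspondence is given, and point-to-point is the measurement that is
exactly zero under perfect symmetry. Because reflections about different
planes differ only by a rigid motion that the subsequent Procrustes step
absorbs, the choice of mirroring plane does not affect the field.

**Lateralization.** Left-sided palsy captures are mirrored (rest and peak)
so the deficit is always on the right half-face; mirroring preserves
distances, so asymmetry is unchanged while the movement deficit switches
sides. This halves the variability the network must model.

## The synthetic cohort generator

The study conditions are 16 patients with unilateral palsy plus 16 controls,
five voluntary expressions each (160 captures), graded by 7 assessors in 2
sessions. Real capture data of this kind are not distributable, so the
generator produces a cohort with the same structure and the geometric
features the pipeline depends on:

- **Template** — a parametric face-like surface (elliptic dome with nose,
  brow, eye-socket, lip and cheek features) sampled on a symmetric grid with
  exactly 7859 vertices by default; every feature enters through `x²` or
  `|x|`, so the mesh is exactly mirror-symmetric and the symmetry pairing is
  exact by construction. It is a geometric stand-in, not an anatomical scan:
  the pipeline needs correspondence, symmetry and regional structure, not
  anatomical fidelity.
- **Expression bases** — smooth symmetric displacement fields localized to
  the anatomically relevant region (brow raise, lid closure, mouth-corner
  excursion, cheek inflation, lip protrusion) with peak magnitudes of
  6–8 mm, matching the 0–10 mm range of real control movement maps.
- **Severity model** — on the affected side the basis is attenuated by
  `a(g) = (g − 1)/4`: grade 5 moves normally, grade 1 not at all, linear in
  between. The law is a modelling choice (no quantitative grade→movement
  mapping is published); linearity makes recovery testable. The affected
  side is selected by a smooth sigmoid across a 5 mm midline band. Ten
  percent of the lost movement reappears mirrored on the healthy side
  (synkinesis-like compensation), and patients carry a resting droop of
  0.35 mm per grade step below 5. Patient grades are integers: an overall
  level uniform on 1–4 with sporadic ±1 per-expression deviations.
- **Nuisance factors** — per-subject symmetric shape perturbations (mirrored
  Gaussian bumps, ~1.2 mm), independent random head poses per frame
  (rotations ≤ 5°, translations ≤ 10 mm, later removed by the alignment
  chain) and isotropic Gaussian sensor noise (σ = 0.1 mm). An optional
  corneal-dropout mode adds extra noise in the eye region during eye
  closure, mimicking poor stereo reconstruction on the reflective cornea
  (off by default).
- **Rater panels** — each of the 14 observations is drawn from a
  discretized-Gaussian ordinal confusion model centred on the true grade
  (default σ = 0.3, at which the 14-observation mode almost always recovers
  the truth). Consensus is the mode; ties break to the smaller (more
  severe) grade, a deliberate conservative-clinically rule recorded in the
  output.

What the generator does **not** emulate: anatomical shape variation beyond
smooth bumps, non-rigid capture artefacts, correlated (non-isotropic) sensor
noise, temporal dynamics within an expression, bilateral or segmental palsy,
and systematic rater biases. Passing tests therefore demonstrate that the
pipeline recovers graded unilateral attenuation under realistic noise and
pose nuisance — a mechanism check — not clinical performance on real faces.

Side-resolved summaries (for example the affected/healthy movement ratio)
are computed over the expression's *active region* — vertices where the
symmetric basis exceeds 20% of its peak — excluding a 10 mm midline band.
Averaged over a whole half-face, the static remainder of the face and the
sensor-noise floor dilute these ratios; the active region is where the
movement, and hence the deficit, physically lives.

## Dataset construction

Each capture becomes a sample: rest cloud (template frame), peak cloud
(rest frame), expression one-hot, consensus grade target. Augmentation
produces 6 variants per original (the unmodified original plus 5 copies),
each rotated by one uniform yaw angle within ±15° about the vertical axis
through the rest-cloud centroid — the same rotation for both clouds — plus
independent Gaussian coordinate noise with σ = 2% of the rest cloud's size.
"Size" is the RMS vertex distance from the centroid by default (a
bounding-box-diagonal alternative is selectable); 160 originals thus become
960 samples. The split assigns originals 80/20, stratified by expression and
cohort, and every augmented variant follows its original into the same
partition, so near-duplicates never straddle the split: 128 × 6 = 768
training and 32 × 6 = 192 test samples. A `naive` mode that splits the flat
augmented list at random is available for comparison.

## The network

Two parallel branches with identical shapes but separate weights embed the
rest and peak clouds. Each branch is a shared per-point MLP
(3→64→64→128→1024, batch normalisation + ReLU after every linear map)
followed by max aggregation over the points into a 1024-dimensional global
feature — the PointNet construction, which makes the output exactly
invariant to point order. No learned input/feature transforms (T-nets) are
used: the clouds are already Procrustes-aligned, which serves the same
purpose. The two global features are concatenated with the expression
one-hot (2053 inputs) and passed through a 512→256 fully-connected head
(BN + ReLU) with a 5-unit linear output, one severity score per expression.
The final bias initializes at 3, the centre of the grade scale.

The loss is the half mean squared error of the score at the sample's own
expression slot. Supervising only that slot (rather than replicating the
target across all five outputs, which is selectable) follows from the
expression identity being an *input*: the other four slots are
counterfactual scores with no target. Adam (learning rate 1e-3,
β = 0.9/0.999) with batch size 8 gives 96 iterations per epoch on 768
training samples. Two standard training refinements matter at this batch
size. First, the learning rate drops by 10× for the final quarter of the
epochs: with batch 8 the gradient noise floor at the initial rate
dominates late convergence. Second, the weight matrices carry an L2
penalty (1e-4, the conventional default of mainstream training
frameworks; biases and BN parameters are exempt): the augmented variants
of each capture are fixed rather than redrawn every epoch, and without
regularisation the network memorizes their specific noise instead of the
smooth severity mapping. Training records per-epoch RMSE and loss; a
non-finite loss aborts with the history attached.

Batch-norm inference uses running statistics. Because the head normalizes
over only 8 rows per training batch, momentum-smoothed running statistics
are a poor match for the normalisation the weights were actually trained
under; after the last epoch the statistics of every BN layer are therefore
recomputed exactly over the training set with large calibration batches
("precise BN"). [train_pointnet] does this automatically and
[calibrate_bn] exposes it.

A prediction is correct when it lies strictly within 0.5 of the consensus
grade; per-expression accuracies, rounded-grade confusion matrices, MSE and
R² make up the evaluation report.

## Numerical and scale choices

- Degeneracy tolerance: second singular value < 1e-12 × largest rejects the
  fit as degenerate.
- BN variance floor 1e-5; Adam ε = 1e-8.
- Mode ties break to the smaller grade; the tie flag is carried in output.
- Point subsampling for training uses one fixed uniform index set per model
  (stored in the model for evaluation), keeping the two clouds of a sample
  on the same vertices.
- Problem sizes for the packaged experiments: the acceptance run trains on
  the default 16 + 16 cohort with clouds subsampled to 128 of the 7859
  vertices for 60 epochs — the point where the training-loss curve
  plateaus on this cohort — and evaluates on the 192 held-out samples.
  The test suite uses the same scale for the recovery check (at 50
  epochs) and smaller meshes (300–800 vertices) elsewhere.
- The point-count choice is the binding constraint on accuracy, not a
  neutral one. The augmentation noise (2% of the ~68 mm cloud size, i.e.
  ~1.4 mm per coordinate) is comparable to the ~2 mm movement difference
  between adjacent grades, so per-sample grade information must be
  recovered by averaging over many vertices; subsampling to 128 points
  leaves substantial subsample-and-noise variance in the max-pooled
  features and therefore in the predicted grade. At full 7859-vertex
  resolution this variance is negligible, but a full-resolution training
  run is outside a single-CPU desk budget. Accuracies produced at the
  packaged scale should be read accordingly: the pipeline demonstrably
  recovers the severity signal (held-out R² and the monotone
  grade-response probe), while the strict |error| < 0.5 per-expression
  accuracy remains below what full-resolution training would give.
- The split keeps all augmented variants of a capture in one partition. A
  flat random split of the 960 samples (the selectable `naive` mode)
  instead places near-duplicates of most training captures in the test
  set; accuracies measured that way are upper bounds inflated by leakage,
  which is why the leakage-safe split is the default even though it makes
  the benchmark markedly harder.

## Limitations

- The synthetic generator, not real capture data, defines the test
  conditions; results demonstrate mechanism, not clinical validity.
- The attenuation law is linear by assumption; real palsy shows regional and
  synkinetic patterns only crudely approximated here.
- Only unilateral palsy is modelled; resting-symmetry parameters are carried
  in the data model but not predicted.
- The landmark vertices are template indices supplied by the template
  bundle, not re-detected on each face; landmark placement error on real
  conformed meshes is therefore not modelled.
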