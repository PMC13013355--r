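---
title: "Task-aware evaluation of PET/CT lesion segmentations for TNM staging"
author: "TNMseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-aware evaluation of PET/CT lesion segmentations for TNM staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TNMseg)
```

## Why voxel overlap is not the clinical question

Automated lesion segmentation in whole-body FDG PET/CT is usually scored
with voxel-overlap metrics such as the Dice similarity coefficient
(DSC). For oncologic staging these metrics answer the wrong question: a
model can delineate 95% of the tumour burden beautifully and still ruin
the patient-level assessment by missing one solitary distant metastasis
(downstaging a palliative patient into curative-intent surgery) or by
segmenting a benign rib fracture as a bone metastasis (upstaging a
surgical candidate into systemic therapy). TNMseg implements the
evaluation chain that connects segmentation output to those clinical
consequences, in five layers:

1. **Voxel metrics** — DSC, false negative volume (FNV), false positive
   volume (FPV), total metabolic tumour volume (TMTV) and Bland–Altman
   agreement of TMTV.
2. **Lesion metrics** — connected components are matched by overlap;
   detection sensitivity and precision are counted per T/N/M category;
   false positives carry an aetiology taxonomy (physiologic uptake,
   benign causes, pathologic non-oncologic causes).
3. **TNM derivation** — explicit rules derive the patient's T (size
   thresholds + invasion flags), N (nodal station levels, with the
   single/multi-station N2a/N2b subdivision) and M (intrathoracic
   spread vs extrathoracic multiplicity) categories from a lesion set.
4. **UICC stage grouping** — a versioned, schema-validated lookup maps
   TNM triples to the ordinal stage scale IA1 … IVB (9th edition
   encoding shipped as `inst/extdata/stage_rules_ninth_edition.json`).
5. **Stage migration** — ground-truth and prediction-derived stages are
   compared per patient; migrations are classified by direction and by
   how many treatment decision boundaries they cross.

Because each layer only consumes the outputs of the previous one, the
same code path evaluates real mask pairs read from NIfTI and synthetic
phantom cohorts.

## The matching model and its conventions

A *lesion* is a connected component of a positive label, under
26-connectivity by default (6 and 18 are available; published challenge
evaluations do not agree on one convention, so it is a parameter). Every
delineated component is a lesion irrespective of size — no minimum-size
filter exists anywhere in the package, deliberately: tiny spurious
components are exactly the false positives the taxonomy is meant to
count.

A predicted component is a true positive when it shares at least one
voxel with a ground-truth lesion (an optional IoU threshold is off by
default). This operationalizes the zero-overlap definitions behind FNV
(volume of ground-truth lesions with no overlapping prediction) and FPV
(volume of predicted components with no ground-truth overlap). One
predicted component overlapping several ground-truth lesions is a
*merge event*: it detects all of them (each counts toward sensitivity)
but appears once in the precision denominator. This matters clinically:
fusing a central primary tumour with adjacent hilar N1 nodes is not a
detection failure, but it deletes the nodal component from the
prediction-derived stage and inflates the measured T size — precisely
the hilar failure mode the phantom can inject.

Two conventions are worth stating because masks alone do not determine
them:

* **Both-empty Dice is 1.0** (with a warning). Agreement on the absence
  of disease should not be penalized; the value is a parameter for
  users who prefer 0 or NA.
* **Diameter is the maximal axial in-plane extent** plus one voxel
  width, not a 3D Feret diameter, because clinical T-size is measured
  on axial sections. A single voxel therefore measures one voxel width.

Percentages are rounded to one decimal, half away from zero,
everywhere — base R's round-half-to-even would disagree with clinical
reporting on exact .05 boundaries.

A limitation flagged openly: expert readings define true positives by
*interpretation* ("read as malignant"), which an overlap criterion can
only approximate. The package's matching is a geometric proxy for a
judgement call; sidecar aetiology annotations exist precisely to carry
the interpretive layer alongside the masks.

## Staging rules as data, not code

The staging tables are a JSON document validated on load: size
thresholds must be strictly increasing; the UICC lookup must be total
over the full T×N×M cross-product (a missing cell is reported by name);
and the stage group must be non-decreasing whenever exactly one of
T/N/M increases — an invariant checked exhaustively both at load time
and in the test suite. Swapping editions means swapping a data file.

Decisions made where the published tables are silent:

* **No primary lesion gives Tx**, not T0 — primaries can be PET-occult
  (lepidic adenocarcinomas with no significant FDG uptake). The lookup
  defines Tx rows explicitly, mapping them like T1a so that a patient's
  stage remains driven by nodal and metastatic burden and the stage
  scale stays fully ordinal for migration analysis. In T confusion
  matrices Tx keeps its own row and column.
* **Invasion flags come only from metadata** (sidecars), never from
  masks: infiltration assessment requires anatomical CT correlation
  that is out of algorithmic scope here.
* **N2a vs N2b** is decided by the number of distinct involved N2
  stations. Because published confusion matrices do not always commit
  to the subdivision, cohort reports can collapse N2a/N2b into one N2
  row (`collapseN2 = TRUE`).
* **M multiplicity**: one extrathoracic lesion is M1b; two or more
  extrathoracic lesions are M1c even within a single organ;
  intrathoracic-only spread (contralateral lung, pleural or pericardial
  involvement) is M1a.

## Decision boundaries and impact levels

The default boundaries are IB|IIA (adjuvant systemic therapy becomes
routine above it) and IIIC|IVA (curative-intent multimodal treatment
gives way to palliative systemic strategies). Impact is a pure function
of the boundary count: High = both boundaries crossed, Moderate = one,
Low = discordant within a band, None = concordant. Treatment semantics
beyond the boundary count ("within the same treatment modality") are
documentation, not computation — the count fully determines the
published table structure this mirrors.

## What the phantom emulates — and what it does not

The generator places **spherical** lesions in disjoint axis-aligned
compartment boxes, each box tied to a category and a station/organ
label. Spheres are a deliberate choice: volume and diameter are then
analytically known, so every downstream measurement has a closed-form
oracle. The error injector then applies, in order: per-category lesion
deletions, a multiplicative volume bias, per-lesion erosion/dilation
(an erosion that annihilates a lesion is logged as an implicit
deletion), an optional hilar merge (a bridging corridor fusing one
primary with one N1 node), and taxonomy-tagged false-positive spheres
placed clear of every true lesion. Every operation is written to an
injection log, and the sidecar carries the false positives' aetiology
with a marker point — mirroring the expert annotation step — so the
evaluator never reads the log itself.

Default parameters are calibrated to the aggregate error profile of a
published expert re-reading of a 306-patient treatment-naive NSCLC
cohort wherever that profile pins them down: per-category deletion
rates 14/425 (T), 25/853 (N), 30/578 (M); per-patient false-positive
means 22/306 (T), 37/306 (N) and, for M, 58/306 physiologic + 70/306
benign + 68/306 pathologic; hilar merge rate 0.111. Image-level
parameters have no published counterpart and were fixed once at
realistic values: a 64×64×80 grid at 3 mm isotropic spacing, lesion
radii uniform in 4–9 mm, Poisson lesion counts tuned to the cohort's
per-patient lesion load (≈1.4 T, 2.8 N, 1.9 M), and an invasion-flag
probability of 0.1.

The phantom does **not** emulate: anatomy or texture (no intensity/SUV
channel exists — everything in scope operates on masks), PET noise,
attenuation, respiratory motion, non-spherical or infiltrative lesion
shapes, overdispersed per-patient lesion counts, or inter-reader
variability in the ground truth. Passing phantom tests therefore
demonstrates that the *evaluation machinery* is correct — that injected
errors are recovered exactly and propagate to staging as designed — not
that any segmentation model performs well on real patients.

## Numerical choices and degenerate inputs

* Geometry is canonicalized on read ("RAS"); matching happens in voxel
  space after asserting equal grid shape and spacing. Mismatched grids
  are rejected, never resampled — silent resampling would change the
  metrics it is supposed to measure.
* Compartment boxes are 0-based half-open voxel intervals, so box
  volumes are exact products of extents; volumes in mL are
  `voxel count × voxel volume (mm³) / 1000`.
* Sphere placement uses bounded rejection sampling with a two-voxel
  clearance margin; a compartment that cannot host a requested lesion
  raises a placement error rather than degrading silently.
* Category assignment ties (a false positive straddling two
  compartments equally) break by the compartment nearest the component
  centroid; components outside every compartment default to category M,
  because the extrathoracic search space is where false positives
  concentrate.
* One master seed drives everything; per-patient streams are derived
  by fixed offsets, so regenerating patient *k* alone reproduces its
  masks bit-identically.
* Bland–Altman uses the sample (n−1) standard deviation and the 1.96
  multiplier, and requires at least two pairs.
* A category with zero ground-truth lesions reports sensitivity as
  missing (NA), never as 0; false positives without aetiology are
  tallied as "unannotated", never dropped.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise: oracle equivalence
of Dice/FNV/FPV on 200 random volumes up to 20³ against brute-force
re-implementations; a 50-patient zero-error cohort, which must come out
perfect end to end (DSC 1.0, sensitivity = precision = 100%, 100% UICC
concordance); a 200-patient cohort with a known injected deletion rate
of 0.2 and Poisson false-positive plans, whose recovered rates must sit
within three binomial standard errors and whose false positives must be
recovered exactly, taxonomy included; exhaustive totality and
monotonicity scans of the staging lookup; and exact recomputation of
every ratio statistic derivable from the bundled 306-patient count
tables (`inst/extdata/nsclc306/`). These sizes keep the whole suite
under a minute on one CPU while leaving the binomial bounds tight
enough to be meaningful.

## Known limitations

* Overlap-based matching approximates interpretation-based reading (see
  above).
* The 9th-edition encoding covers the category set the pipeline can
  produce (Tx, T1mi–T4, N0–N3 with N2a/b, M0–M1c); finer M1c
  subdivisions (single vs multiple organ systems) are collapsed into
  M1c, matching the coarser reporting this package targets.
* Histology-specific staging, resectability, treatment recommendation
  and oligometastatic concepts are out of scope by design.
* CSV/JSON sidecars and NIfTI are the only formats; DICOM-SEG and
  RTSTRUCT are not read, and no resampling or registration is offered.
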