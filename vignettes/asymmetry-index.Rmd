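---
title: "A distance-based signed index of 3D facial asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A distance-based signed index of 3D facial asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceasym)
```

## The measurement problem

Quantifying facial asymmetry from 3D-CT usually starts by constructing a
coordinate system: a midsagittal plane, a horizontal plane, a coronal plane,
each chosen by the clinician. Every downstream number then depends on those
choices, and two clinicians can disagree about a patient's asymmetry simply
because they chose different reference planes. `faceasym` implements an
alternative: an asymmetry score per anatomical landmark built **only from
inter-landmark distances**, so it is invariant under any rigid motion of the
head in the scanner and requires no axis convention at all. Coordinates may
arrive in any rigid frame; patient left and right are carried by explicit
side labels, never by the sign of an axis.

## The index

Fourteen named landmarks are used (see `landmark_names()`). Five are cranial
reference points assumed stable under orthognathic surgery: sella (S),
nasion (N), the two frontozygomatic suture points (Z, one per side) and the
two porions (Po). MidZ, the midpoint of the Z pair, is always derived, never
digitized. The remaining ten are measurement points: five bilateral pairs
(orbitale Or, condylion Co, gonion Go, first molars U6/L6) and five midline
points (ANS, incisor contact points U1/L1, B point, menton Me).

**Bilateral landmarks.** For a pair \(P_L, P_R\) and the three midline
references \(r \in \{S, N, \mathrm{MidZ}\}\), form the distance differences
\(d_r = \lVert r - P_L \rVert - \lVert r - P_R \rVert\). The index magnitude
is

\[ \mathrm{FAI} = \sqrt{d_S^2 + d_N^2 + d_{\mathrm{MidZ}}^2}, \]

which is zero exactly when the pair sits in a 3D-symmetric position with
respect to the three (non-collinear) references. The deviation *direction*
is the side whose perpendicular distance to the N–S–MidZ plane is longer.

**Midline landmarks.** For a point \(m\), the references are the two
bilateral cranial pairs: \(d_Z = \lVert Z_L - m \rVert - \lVert Z_R - m
\rVert\) and \(d_{Po}\) analogously, with
\(\mathrm{FAI} = \sqrt{d_Z^2 + d_{Po}^2}\) — zero exactly when \(m\) is
equidistant from both members of both pairs, i.e. on the true midsagittal
plane of the cranial base.

**Sign convention.** Left deviation is positive, right deviation negative.
For midline landmarks the source describes the convention but not the
computation; we take the sign of the summed right-minus-left distance
differences: a point deviated to the left is closer to the left-side
references, making that sum positive. This agrees with the bilateral rule's
geometry on every case we can construct.

```{r worked}
s <- generate_landmarks(displacements = data.frame(
  name = "Me", side = "M", dx = 6, dy = 0, dz = 0))
midsagittal_index(s, "Me")
```

### Direction "none" and vertical asymmetry

The magnitude responds to asymmetry along *any* axis, but the sign encodes
transverse deviation only. A gonion displaced 6 mm purely vertically has a
large index (≈ 8.62 mm on the template) yet identical perpendicular
distances to the midsagittal plane on both sides. Rather than invent a side,
the package reports `direction = "none"` (tie tolerance `1e-6` mm, far below
clinical or numerical relevance) and carries `+` on the signed value by
convention. Whether the original method would assign a side here is not
stated; exposing the tie is the honest choice.

### Properties the test suite enforces

* **Rigid invariance** — magnitudes, directions and signed values are
  unchanged under any rotation + translation (tested over 500 random
  transform/set combinations at 1e−6 mm).
* **Label-swap antisymmetry** — relabelling L↔R without moving a point
  negates every signed value. Reflecting the set across the N–S–MidZ plane
  *without* relabelling changes nothing, because reflection is an isometry
  and the index uses only distances; the anatomical mirror (reflect +
  relabel) therefore negates signed values while preserving magnitudes.
* **Scaling** — scaling all coordinates by \(k > 0\) scales every magnitude
  by \(k\) (the index is in mm, not normalized).
* **Zero characterization** — a bilateral index is zero iff the right point
  coincides with the left point or with its mirror image across the
  reference plane.
* **Oracle equivalence** — every computed value matches an independent
  brute-force recomputation from raw Euclidean distances within 1e−9 mm.

## Normative ranges and classification

The packaged `normative_table()` carries the mean and SD of the *absolute*
index per landmark from a 25-subject normal standard group (adult males with
normal occlusion, clinically balanced faces, menton within 4 mm of the
midsagittal plane). Means range from 1.77 mm (ANS) to 3.38 mm (Co) —
nonzero even in symmetric faces, because landmark placement error alone
produces a positive index (the synthetic generator reproduces this: pure
0.5 mm placement noise yields strictly positive indices). A landmark is
called *asymmetric* when \(|\mathrm{index}| > \bar{x} + z \cdot s\).

The band description behind the threshold ("mean plus SD, p = 0.05") is
ambiguous between \(z = 1\), \(1.96\) and \(2\); we default to **1.96** (the
two-sided 5% normal quantile) and make \(z\) configurable everywhere
(`normative_table(z=)`, override files, `--z`), so every reading is
reachable. Boundary values classify as symmetric (strict `>`), reading the
coloured band of the reference chart as inclusive of its outline. The
cohort screen `menton_screen()` uses strict `< 4` mm, the literal "under
4 mm" rule. Note the cohort is male-only; no sex- or age-specific tables
exist.

## Reliability statistics

`dahlberg_error()` implements the cephalometric method error
\(SE = \sqrt{\sum d^2 / 2n}\) over paired double measurements;
`paired_t_test()` is the standard two-sided paired t test (two-sided is the
field default when sidedness is unstated). Identical series are reported as
an explicit error rather than \(t = \infty\). Pairing uses signed values by
default — signs are part of the measurement — with magnitudes available via
`use = "magnitude"` since the original 100 double-measured indices are not
described either way.

## The synthetic generator: what it emulates and what it does not

Patient CTs are unavailable, so testing rests on `generate_landmarks()`: a
bilaterally symmetric template (`skull_template()`, 21 points at realistic
craniofacial positions, left = +x by construction only), plus

1. named per-landmark displacement vectors — the ground-truth asymmetry;
2. isotropic Gaussian placement noise per coordinate (default 0 in the
   generator; tests use 0.5 mm, a typical landmark identification error on
   1 mm-slice CT);
3. a rigid pose (intrinsic z–y–x rotation in degrees, then translation),
   emulating arbitrary head position in the scanner.

Noise is applied before the pose — it models landmark-picking error in the
scanner frame; for isotropic noise the order is statistically irrelevant but
must be fixed for seeded reproducibility. The generator emulates landmark
geometry only: no anatomical shape variation, no growth, no surfaces, no
correlated placement errors, and displacement vectors move single landmarks
rather than bony segments. A green test therefore establishes the *computational*
contract (the formula, its invariances, recovery of known displacements
under noise) — it cannot validate clinical accuracy against real CTs, and
the packaged normative constants are used as published, not recomputed.

## Reporting

`compare_profiles()` tabulates pre/post change; *improvement* is
\(|pre| - |post|\), so a B point moving from +7.28 to −1.45 mm counts 5.83 mm
of improvement despite crossing the midline, matching how surgical cases are
narrated. `render_chart()` draws the polygonal (radar) chart: ten axes in
the fixed order Or, Co, ANS, U6, U1, L1, L6, Go, B, Me (the normative
table's row order; the original figure's axis order is not legible from the
text, so this is a package convention), signed values with the zero line at
mid-radius, mirrored bands at ±mean (green) and ±(mean + z·SD) (light
green), grey outside = asymmetric. The radial scale auto-fits
max(|value|, max threshold) + 10%, since severe cases (±16 mm and more) far
exceed the normative bands. SVG output is hand-written text and
byte-deterministic; first profile red, second blue (pre/post convention).

## Numerical choices

* Collinearity of the three plane-defining points: triangle area
  < 1e−6 mm² is an error (landmarks live at 10–100 mm scale).
* Plane orientation comes from a left-side witness (Z(L), falling back to
  Po(L) if coplanar); if all witnesses are coplanar the plane is rejected.
* Direction tie tolerance 1e−6 mm, configurable via `tol` / `--tolerance`.
* Coordinates are serialized with 17 significant digits so read∘write is
  exact well beyond the 6-decimal contract.
* Seeds: `generate_landmarks()` restores the caller's RNG state, so library
  use never perturbs a user's random stream.

## Known limitations

The index attributes all distance-difference signal to the measurement
landmark, assuming the five cranial references are themselves symmetric and
surgically stable; reference asymmetry (e.g. orbital or cranial-base
deformity) contaminates every downstream value. Serial comparisons assume
pre- and post-operative landmark sets arrive in one common frame (volume
registration of the CTs is out of scope and must happen upstream). Angular
measures (ramal inclination, occlusal canting angles) and mirror-image
surface similarity analyses are different methods and deliberately not
implemented.
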