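---
title: "The NIfTI-MRS format in mrsnifti: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NIfTI-MRS format in mrsnifti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsnifti)
```

## The data model

In-vivo magnetic resonance spectroscopy (MRS) acquires a complex
time-domain signal — the free induction decay (FID) — rather than an image.
Yet almost everything *around* the signal (voxel placement, orientation,
co-registration with structural MRI, viewing tools) is shared with imaging.
The NIfTI-MRS standard therefore stores spectroscopy inside a NIfTI-2 file:

* **Data block**: a complex array of rank 4–7. Dimensions 1–3 are spatial
  (all singleton for single-voxel data), dimension 4 holds the FID samples,
  and dimensions 5–7 optionally hold "dynamic" series — uncombined receive
  coils, repeated measurements, editing conditions, and so on. Seven is a
  hard ceiling inherited from the parent NIfTI format. Only the complex
  datatypes are allowed: single precision (NIfTI code 32, the writer
  default here) or double precision (code 1792).
* **Header**: the ordinary NIfTI-2 header, reinterpreted in places. The
  dwell time (the FID sampling interval, reciprocal of the spectral
  bandwidth) lives in `pixdim[4]`, with units declared in `xyzt_units`
  (this package always writes millimeters/seconds, code 10). The standard's
  version is carried in `intent_name` as `mrs_v{major}_{minor}`; this
  implementation writes `mrs_v0_6` and reads any version, warning (not
  erroring) when a file declares a newer one.
* **Header extension**: a JSON object in a NIfTI extension record with
  code 44. This is where all spectroscopy-specific metadata lives.

An `mrs_image` bundles these three parts; `mrs_make_minimal()` builds a
conformant one from nothing but an FID, the dwell time, the spectrometer
frequency and the nucleus.

## Metadata: four kinds of key

The extension distinguishes exactly four key categories
(`classify_key()`):

1. **Mandatory** — `SpectrometerFrequency` (MHz) and `ResonantNucleus`.
   Both are stored as arrays (a file can interleave nuclei), and both are
   required for any meaningful interpretation of the data. Nothing else
   is load-bearing on a minimal file.
2. **Dimension** — `dim_{n}`, `dim_{n}_info`, `dim_{n}_header` for
   n = 5, 6, 7. `dim_{n}` is mandatory as soon as the dimension is used
   (size > 1) and takes a tag from a fixed vocabulary (`DIM_COIL`,
   `DIM_DYN`, `DIM_INDIRECT`, `DIM_EDIT`, `DIM_ISIS`, `DIM_PHASE_CYCLE`,
   `DIM_MEAS`, `DIM_USER_{0–2}`). The vocabulary ships as an editable
   table (`inst/extdata/dim_tags.tsv`) so later revisions can extend it
   without code changes. `dim_{n}_header` attaches per-element metadata:
   either a long-form array whose length must equal the dimension size, or
   a compact `{start, increment}` progression, optionally wrapped as
   `{Value, Description}`. Compact forms are accepted on read and expanded
   to long form when set through `set_dim_tag()`, so written files are
   canonical. `get_dim_header_value()` uses **0-based** element indices,
   matching the on-disk convention rather than R's 1-based habit.
3. **Standard-defined** — keys with fixed meaning, type, units and a
   privacy flag, shipped as a data table
   (`inst/extdata/standard_keys.tsv`). The registry is deliberately data,
   not code: the authoritative key list lives in the standard document and
   evolves; reconciling it is an edit, not a refactor. `mrs_edit_key()`
   type-checks standard keys against the registry.
4. **User-defined** — everything else, arbitrarily nested JSON. The
   validator warns (never errors) on capitalized unknown keys, since they
   are usually typos of standard keys but are explicitly permitted.

Processing provenance is a fifth, structural element: `ProcessingApplied`
is an ordered list of `{Method, Program, Version, Details}` entries
(`append_provenance()`); converters append exactly one.

## Anonymization

Standard-defined keys carry a privacy flag; user keys self-mark by the
`private_` name prefix at any nesting depth. `mrs_anonymize()` deletes —
never masks — every such key wherever it occurs (standard keys, nested
user objects, dynamic headers, provenance details), reports dotted paths
of what it removed, and leaves the data array untouched bit-for-bit. The
mandatory keys are never removable, so anonymization cannot break
conformance, and the operation is idempotent. Which keys count as
identifying is a policy choice: this registry conservatively flags all
subject identifiers and quasi-identifiers (`PatientName`, `PatientID`,
`PatientDoB`, `PatientSex`, `PatientWeight`) plus `DeviceSerialNumber`,
`InstitutionAddress`, `AcquisitionStartTime` and `OriginalFile` (source
filenames often embed subject names). Sites with different policies edit
the table.

## Spatial information

Voxel geometry follows NIfTI: a qform (quaternion b, c, d + offsets +
per-axis scales + the handedness sign `qfac` stored in `pixdim[0]`) and/or
an sform (a bare 3×4 matrix). The quaternion reconstruction uses the
NIfTI-1 reference formula with `a = sqrt(max(0, 1 − b² − c² − d²))`; the
inverse decomposition extracts positive column scales, flips `qfac` when
the rotation block is left-handed, and refuses shear beyond 1e-5 (the
qform cannot represent it). Round-tripping random rigid affines
reproduces every element to well below 1e-9.

Policy choices where the standard allows latitude:

* qform is authoritative on read; if a populated sform disagrees beyond
  1e-3 mm a warning is raised. On write the sform is mirrored from the
  qform for maximal viewer compatibility; authoring genuinely distinct
  dual frames is left as a manual header edit.
* Spatial units are millimeters. Unlocalized data (simulations, data
  localized only by coil sensitivity) is written with `qform_code = 0`
  and the standard's default voxel size of 10 m — stored as 10000 mm;
  `voxel_size_m()` converts back.
* Voxel indices are 0-based with coordinates at voxel centers (NIfTI
  convention).
* NIfTI cannot represent gaps between voxels or slices in one file;
  `check_contiguity()` implements the dense-rectilinear-lattice test
  converters use to refuse multi-slab input. The voxel size is part of the
  grid specification (`spacing`): two evenly spaced slices cannot reveal a
  gap by their origins alone.

## Frequency and phase conventions

The standard fixes a display convention: the absolute (rotating-frame
offset) frequency axis increases left to right, hence the chemical-shift
(ppm) axis increases right to left. `ppm_axis()` produces DFT-shifted
offsets spanning `[-BW/2, +BW/2)` ascending, with
`ppm = ref_shift − offset / f0` — so ppm strictly decreases left to right
with slope `−1/f0`. A resonance at shift δ is synthesized and interpreted
with offset `f = (ref_shift − δ)·f0`, which places less-shielded nuclei
(higher ppm) on the left for γ > 0 nuclei; γ < 0 nuclei use the same
storage rule. The time-domain statement of the convention is operational
as `flip_frequency_convention()` (element-wise conjugation, mirroring the
spectrum about zero offset).

The reference shift is a display parameter, never hard-coded in the math:
`default_ref_shift()` returns 4.65 ppm (water at body temperature) for 1H
and 0 otherwise, and every axis-producing function takes it as an
argument.

DFT normalization: forward unnormalized, `1/N` on the inverse
(`fid_to_spectrum()` / `spectrum_to_fid()`); Parseval's identity
`Σ|fid|² = Σ|spectrum|²/N` is asserted in the tests. First-order phasing
(`apply_phase()`) is parameterized in radians per Hz about a pivot
frequency (default: zero offset); the pivot bin is invariant under any
first-order phase.

## Converters

Only text formats with no binary or vendor ambiguity are converted:
LCModel RAW/H2O (FORTRAN namelist header + real/imaginary pairs), jMRUI
text, and plain two-column ASCII. None of them carries orientation, so
conversions always get the unlocalized default geometry, and whatever the
format omits must arrive via `conversion_overrides()`. Field mappings are
self-authored (the reference converter's internal mappings are not
documented): `HZPPPM` → `SpectrometerFrequency` (Hz-per-ppm is
numerically MHz), `DELTAT` → dwell (s), `ECHOT` (ms) → `EchoTime` (s);
jMRUI `SamplingInterval` is ms → s and `TransmitterFrequency` Hz → MHz.
jMRUI files with more than two numeric columns contribute only the first
two (the FID; spectrum columns are derivable). Multi-signal jMRUI files
stack into dimension 5 tagged `DIM_USER_0`. Every conversion appends
exactly one provenance entry and is deterministic — no timestamps are
written, so identical input bytes and overrides give identical files.

## The synthetic generator

`simulate_fid()` produces a sum of Lorentzian lines,

$$ s(t_k) = \sum_p A_p e^{i\varphi_p}\, e^{i 2\pi f_p t_k}\, e^{-\pi\,\mathrm{lw}_p t_k},
 \qquad f_p = (\mathrm{ref} - \delta_p)\, f_0, $$

with complex Gaussian noise of per-component standard deviation σ from a
seeded generator that saves and restores the caller's RNG state. The
linewidth parameter `lw` is the FWHM (Hz) of the **absorption** (real)
lineshape; the magnitude lineshape of the same line is √3 wider, which is
why the linewidth test measures the real part. A zero-noise FID has mean
power 2σ² under noise alone, checked by Monte-Carlo at 10⁵ points within
three standard errors.

`gen_example()` emulates the four structural archetypes of published
example data: raw single-voxel 1H (coils × dynamics), processed 31P MRSI
with privacy-flagged subject keys and provenance, spectral editing with a
per-element `EditCondition` dynamic header on dimension 7, and a
"fingerprinting" series where four acquisition parameters
(`EchoTime`, `RepetitionTime`, `ExcitationFlipAngle`, `InversionTime`)
co-vary along one `DIM_USER_0` dimension — the case where parameters do
not form a dense grid and so cannot each take a dimension of their own.
Sizes are deliberately small (N ≤ 1024, grids ≤ 8×8, ≤ 16 dynamics) so the
whole suite — including a 200-file round-trip sweep and a 1000-affine
geometry sweep — runs in seconds; these problem sizes are the package's
own choice of test scale. Simulated acquisition parameters (3 T-like
123.2 MHz for 1H, 49.9 MHz for 31P, 2 kHz bandwidth, 4–14 Hz linewidths)
are typical in-vivo values. What the generator does **not** emulate:
metabolite multiplets from spin Hamiltonians, macromolecule baselines,
frequency drift, or realistic coil sensitivity maps — passing tests say
the *format machinery* is sound, not that downstream processing of real
data would succeed.

## Numerical choices and degenerate inputs

* JSON numbers are serialized with 17 significant digits, the minimum
  guaranteeing IEEE-754 double round-trips; serialize→parse is exactly
  invertible.
* Extension records are padded with NULs to the next multiple of 16 bytes
  (the NIfTI rule); padding is stripped on read before JSON parsing.
* Single-precision storage quantizes each component through IEEE float32;
  `as_complex64()` exposes that quantization so callers can predict
  bit-exact round trips.
* Trailing singleton dimensions are preserved as declared; a size-1 tagged
  dynamic dimension is legal and keeps its tag.
* Zero-length FIDs, non-positive dwell times, quaternions with
  `b²+c²+d² > 1 + 1e-6`, sheared affines and vocabulary violations are
  rejected with classed errors rather than warnings.
* Files are written little-endian; big-endian files are byte-swapped on
  read. NIfTI-1 files are read with a warning and upgraded to NIfTI-2 on
  the next write. Exactly one code-44 record is ever written; encountering
  more than one on read is an error (ambiguous metadata), while records
  with other codes are preserved across a read/write cycle.

## Known limitations

Vendor binary formats (Twix, GE p-files, Philips SDAT, Bruker, DICOM
dialects) and k-space reconstruction are out of scope by design — those
belong to dedicated conversion tooling. The conformance rule set
implemented here is the subset stated in the published description of the
standard; the complete checklist in the full standard document may add
rules, which belong in the validator rather than being invented here. The
bundled key registry likewise awaits reconciliation against the full
standard's key list; it is a superset of the documented minimum and is
editable data.
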