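---
title: "Simulating and matching 1D 1H NMR metabolite spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and matching 1D 1H NMR metabolite spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinmatch)
library(ggplot2)
```

## The problem

A metabolite's 1D proton NMR signature is a set of multiplets whose
positions (chemical shifts, in ppm) are field-independent but whose
internal structure is not: scalar couplings are constant in Hz, so the
shape of a multiplet — and, under strong coupling, even its line
positions and intensities — changes with the spectrometer frequency.
Annotation databases that archive only peak lists picked at one field
therefore transfer poorly to spectra recorded at another, and archived
peak lists frequently lack line widths or carry misaligned positions.
spinmatch implements the computational core of a curation workflow for
such data: field-independent simulation from spin-system matrices,
Lorentzian rendering of annotated peak lists, region-of-interest
cosine-similarity scoring against experimental spectra, an automatic
remediation pipeline, and a per-metabolite exchange file format with
InChI-based deduplication. A synthetic-data module generates every
fixture needed to exercise the pipeline, so nothing here requires
downloads from the public archives.

## Quantum-mechanical simulation

A spin system is a vector of proton chemical shifts $\delta_i$ (ppm)
plus a symmetric matrix of scalar couplings $J_{ij}$ (Hz). At a
spectrometer frequency $\nu_0$ (MHz) the isotropic spin-1/2 Hamiltonian
in the product basis is, in Hz,

$$
H \;=\; \sum_i \nu_i I_z(i) \;+\; \sum_{i<j} J_{ij}
\left[ I_x(i)I_x(j) + I_y(i)I_y(j) + I_z(i)I_z(j) \right],
\qquad \nu_i = \delta_i\,\nu_0 .
$$

Conventions the package fixes (the underlying physics literature admits
several equivalent choices): offsets are lab-frame frequencies in Hz
with larger ppm meaning higher frequency, and the detection operator is
$\sum_i I_x(i)$ with squared matrix elements as intensities, normalized
so the total intensity equals the number of spins (an isolated proton
contributes exactly 1, so integrals are proportional to proton counts).

`spin_transitions()` diagonalizes $H$ blockwise by total magnetic
quantum number — which $H$ conserves — and enumerates single-quantum
transitions between adjacent blocks. Weak and strong coupling then
emerge naturally: an AB pair reproduces the textbook closed form
(lines at $\nu_c \pm (C \pm J)/2$ with $C = \sqrt{\Delta\nu^2 + J^2}$
and inner:outer intensities $(1+J/C):(1-J/C)$), and the "roof effect"
asymmetry relaxes monotonically as the field grows from 100 to 900 MHz.

Two numerical knobs exist. Transitions weaker than `intensity_cutoff`
($10^{-9}$ of the strongest) are dropped, and transitions closer than
`merge_tol_hz` ($10^{-6}$ Hz) are merged by intensity-weighted
averaging; both sit far below spectral resolution and exist so that
magnetically equivalent spins collapse cleanly to a single line of
total intensity $n$. The cutoff value is a package decision — the
exact-diagonalization approach itself does not prescribe one.

Cost grows exponentially in the spin count (the largest block has
$\binom{n}{n/2}$ states; producing a peak list is roughly cubic per
transition in practice), so `max_spins` defaults to 12 and larger
systems are refused with an explicit complexity error. Segmented
approximations for larger molecules are deliberately out of scope.

```{r ab-demo}
ab <- spin_system(c(1.00, 1.01), matrix(c(0, 7, 7, 0), 2))
spin_transitions(ab, 600)
```

## Rendering

Peaks carry heights and full widths at half maximum in Hz; rendering
converts widths to ppm (`width_hz / spectrometer_mhz`) and sums
height-parameterized Lorentzians

$$
L(x) = h\,\frac{\gamma^2}{x^2 + \gamma^2}, \qquad \gamma = \tfrac{w}{2},
$$

over a uniform ppm grid stored in decreasing order (the display
convention). The height parameterization matches how source databases
store peak data; areas, when needed, follow analytically as
$\pi h w / 2$. Tails are never truncated, and the renderer adds no
noise or apodization — experimental artifacts belong to the synthetic
module. Grids exactly matching an experimental spectrum's sweep width
and point count come from `render_like()`.

## Similarity scoring

Agreement between a simulation $\vec A$ and an experimental spectrum
$\vec B$ is the cosine similarity
$\vec A \cdot \vec B / (\lVert \vec A\rVert\,\lVert \vec B\rVert)$:
1 for a perfect match, $-1$ for a perfect inversion, invariant to
intensity scaling. It is computed per region of interest (ROI) and
averaged, unweighted, into the overall score, so solvent and reference
signals outside the ROIs cannot contaminate the result.

Scoring constants, and where they come from:

* **Threshold 0.9.** For two co-centered Lorentzians of width ratio
  $r$, the continuum cosine is exactly $2\sqrt{r}/(1+r)$; 0.9
  corresponds to $r = 2.5$, i.e. the threshold tolerates a simulated
  line up to 2.5 times too wide (or narrow) but little more.
* **SNR $\ge$ 10.** Regions whose experimental signal-to-noise ratio —
  maximum region intensity over the standard deviation of a peak-free
  noise stretch — falls below 10 (the accepted limit of
  quantification) are excluded from the mean and listed on the report.
  The rule is applied per region; the noise interval defaults to the
  widest stretch of the grid not covered by any ROI, and the rule is
  skipped when the noise estimate is at the numerical floor (ideal
  noiseless grids). During remediation, if the rule would exclude
  every region it is relaxed to keep a diagnostic score available.
* **ROI construction.** One interval per multiplet: the span of its
  outermost peaks widened by `margin_factor` (default 10) times the
  widest member width, with overlapping intervals merged. The margin
  covers Lorentzian tails without swallowing neighbouring regions.

A note on the score's definition: the subtracted form
$1 - \vec A\cdot\vec B/(\lVert\vec A\rVert\lVert\vec B\rVert)$
sometimes seen in print would give 0 for a perfect match,
contradicting both the 1/−1 range semantics and the width-ratio
calibration above; spinmatch deliberately uses plain cosine
similarity, which is consistent with all three.

```{r score-demo}
pk <- simulate_peaks(make_spin_system(synthetic_spec(seed = 1)), 600)
sim <- render_spectrum(pk, 600, ppm_first = 10, ppm_last = 0,
                       n_points = 4096)
glance(score_spectra(sim, sim, regions_of_interest(pk, 600)))
```

## Automatic remediation

Simulations scoring below threshold are adjusted in a fixed order:
solvent suppression, then global alignment, then global width scaling.
The order is a design choice — solvent contamination corrupts both
other fits, and alignment errors dominate the cosine penalty, so they
are removed first. Details:

* **Solvent suppression** trims ROIs against the residual-water
  (4.6–4.9 ppm) and reference (−0.1–0.1 ppm) regions. Because ROIs are
  *defined* to keep solvent and reference signals out of the score,
  the trimming applies to the before- and after-scores alike; it is
  booked as a pipeline step (with the suppressed intervals on the
  record) whenever remediation actually runs. This also makes the
  bookkeeping invariant exact: a `remediated` record can never have
  `score_after < score_before`, since both optimizers include the
  identity in their search space.
* **Alignment** fits one global ppm offset within ±0.05 ppm (enough
  for DSS/TSP/TMS referencing offsets), by grid search at the axis
  resolution seeded from aligning the lowest-ppm simulated multiplet
  to the nearest experimental maximum, then parabolic-free local
  refinement (`stats::optimize`) around the grid optimum. Offsets at
  the search edge are returned with a bounds warning.
* **Width scaling** fits one multiplicative factor on every width over
  [0.2, 20] (log-scale grid plus local refinement), re-rendering per
  candidate. A global factor, not per-peak widths, is fitted: the
  automatic stage is meant to fix systematic problems such as 1 Hz
  placeholder widths standing in for ~3 Hz experimental lines;
  per-peak edits are manual territory.

Records carry a status — `verified` (already above threshold, no
steps), `remediated`, `needs_manual`, or `unverified` — and a
bookkeeping category matching the usual manual-curation taxonomy
(peak position/height, multiplet pattern, J-coupling, width,
alignment, solvent, unverifiable). A score of exactly 1.0 (within
machine precision) is flagged `unverified` rather than accepted:
perfect scores indicate cleaned or duplicated data rather than an
experimental match, and demand inspection.

## The entry format

Each metabolite is one UTF-8 text file in a documented subset of STAR
syntax (the syntax family of NMR exchange formats): a `data_` block
with one saveframe per relational table — metabolite, synonyms,
ontology terms, concentrations, samples, spectra, multiplets, peaks,
couplings — with `mdb_`-prefixed frame names, explicit loop column
headers, `.` as the null token and numbers written at 12 significant
digits (round trips are exact well beyond 9). The saveframe vocabulary
is this package's own, self-documented dialect; it is
syntax-compatible with generic STAR readers but not claimed identical
to any archive's schema.

Modelling decisions mirrored in the schema: a spin system is stored as
atom-assigned multiplets (one per proton, carrying its shift) plus a
coupling table, so the same tables serve annotated peak lists and
quantum simulations; ontology terms live in a flat table rather than a
hierarchy; missing metadata (pH, temperature, widths) are explicit
nulls, never imputed — missing widths are filled at use time by
`apply_placeholder_widths()` (1 Hz, flagged, so width remediation
knows which values were real). Metabolite-level accessions
(HMDB-style, unambiguous per metabolite) sit on the metabolite table;
sample-level accessions (BMRB-style, ambiguous per metabolite) travel
with their samples. `merge_by_inchi()` deduplicates entries on their
InChI, unioning synonyms, metadata and samples, and renaming
colliding sample/spectrum identifiers with the source entry id.

## The synthetic generator

`synthetic_spec()` fixes every random choice under one seed and
controls what the generated "experimental" spectra contain. Defaults:
4-spin systems with shifts uniform on 0.5–9 ppm and couplings drawn
N(7, 2²) Hz over a random spanning tree (plus occasional extra edges),
so every system is one connected network of typical vicinal couplings;
white noise of 1% of the maximum intensity; a gentle (1%) sinusoidal
baseline; a 1 Hz reference peak at 0.00 ppm and a 20 Hz
residual-solvent Lorentzian at 4.70 ppm. Broadening re-renders from
the peak list when it is known (exact, since Lorentzian widths add)
and otherwise convolves with a Lorentzian kernel; the global ppm
offset is applied by axis re-interpolation. Broadening and shifting
commute, so the implementation renders first and shifts second.

What the generator does *not* emulate — and what green tests therefore
do not demonstrate about real data: macromolecular baselines of
biofluids such as plasma or urine, phase and shimming (non-Lorentzian
lineshape) errors, pH- or temperature-driven shift changes of
individual multiplets, and peak-picking artifacts in dense overlapped
regions.

The recovery study shipped with the tests runs 50 seeded trials at the
documented conditions — offset uniform on ±0.01 ppm, width factor
uniform on [1, 5], 1% noise, 4-spin systems rendered on a 4096-point
grid over 10–0 ppm at 600 MHz — and requires at least 90% of trials to
reach the 0.9 threshold after automatic remediation. These problem
sizes (4096-point grids, 3–5 spins) are the package's chosen study
scale: large enough to resolve 1 Hz lines at 600 MHz, small enough
that the whole suite runs in a few minutes.

## Known limitations

Only spin-1/2 protons are simulated; no relaxation, NOE or dynamic
effects; no Gaussian/Voigt lineshapes; no phase or baseline correction
of experimental data; no automatic J-coupling refitting or per-peak
editing (those remain manual, with the record taxonomy as their
bookkeeping); spin systems above `max_spins` are refused rather than
segmented. The SNR exclusion rule is applied per region of interest —
a per-peak reading of the rule is also defensible, and the choice is
flagged here for review.
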