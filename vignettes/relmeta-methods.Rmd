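---
title: "relmeta: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{relmeta: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmeta)
```

This vignette documents the science and the numerical conventions behind
`relmeta`: what each component computes, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open and a choice had to be made.

## The STAR metadata model

RELION stores all processing metadata in STAR files: named `data_` blocks
holding `_label value` pairs and/or a `loop_` table of whitespace-separated
rows. `relmeta` models a document as an ordered list of blocks, each with
ordered pairs and an optional loop table (a `data.frame`); block order, label
order and row order are part of the value and survive a round trip.

Conventions worth knowing:

* **Typing.** STAR is untyped. A column whose cells all match an integer
  literal becomes `integer`; all-real columns (including scientific
  notation) become `double`; anything else stays text. A single
  non-numeric cell keeps the whole column textual, which matches how
  RELION consumers treat mixed columns.
* **Serialization precision.** Reals are written with six decimal places
  (fixed notation for magnitudes in `[1e-4, 1e7)`, otherwise scientific
  with six digits), mirroring the `%12.6f`-style columns RELION emits.
  Round-trip equality is defined *after* one write: `parse(write(d))`
  equals `d` for any document already at serialization precision, and
  writing is byte-idempotent. The synthetic generator snaps every planted
  real through this representation before returning it, which is why
  recovery tests can compare bit-exactly.
* **Labels.** Stored without the leading underscore; queries are matched
  case-sensitively, with or without the underscore and the `rln` prefix
  (`"CtfMaxResolution"` finds `_rlnCtfMaxResolution`), since prose and
  plot axes conventionally drop the prefix.
* **Comments** are discarded on parse; the writer emits one generated-by
  header line. Quoted strings are supported; semicolon-delimited
  multi-line fields are not (RELION does not emit them). There is no
  missing-value convention in RELION's dialect; the parser simply keeps
  unrecognized tokens as text, and the generator never plants missing
  cells.

## The ice-quality score

Both vitreous and crystalline ice produce intensity maxima in the
micrograph power spectrum in the 3.6–4 Å range, crystalline ice far
stronger. The score of a micrograph is the arithmetic mean of the
rotationally averaged power spectrum over the band
$[1/4,\,1/3.6]\ \text{Å}^{-1}$, both edges inclusive (a closed range
maximizes the handful of Fourier samples that fall inside it). It is a
dimensionless ranking proxy — it deliberately correlates with no single
physical magnitude, since thickness, crystallinity and contamination all
feed the same band.

Two routes produce the profile:

* **CTFFIND profile route** (the cheap default): CTFFIND4 already writes
  the radially averaged spectrum next to each CTF fit ("avrot" files, one
  frequency row plus five signal rows). The default signal row is the
  background-subtracted rotational average (row 3 of the six-row layout):
  background subtraction removes the defocus-envelope trend that would
  otherwise dominate a band mean. The row index is configurable because
  the choice between raw and background-subtracted profiles is a
  convention, not a law.
* **Native route**: `power_spectrum()` (unnormalized DFT,
  center-cropped to square so radial bins stay isotropic, DC centered)
  → `radial_average()` → `band_mean()`. By default the spectrum is
  divided by its total non-DC power first, making the score invariant to
  overall image intensity; with normalization disabled the score scales
  as the square of image intensity (power-spectrum homogeneity), which
  the tests assert.

The two routes agree in *ranking* (their absolute scales differ); the test
suite requires Spearman concordance on a 30-micrograph synthetic set.

Radial averaging bins each Fourier pixel (excluding DC) by its integer
radius — nearest integer, ties at .5 rounded **away from zero** (base R's
`round()` is banker's rounding, which would split tie pixels
inconsistently between bins). The frequency of radius $r$ in an
$n\times n$ spectrum at pixel size $p$ is $r/(np)$; bins beyond Nyquist
($r > n/2$) are discarded. Seeing the ice band at all requires
Nyquist $\ge 0.25\ \text{Å}^{-1}$, i.e. a pixel size of at most 2 Å —
coarser pixels raise an explicit error rather than a silent zero-sample
mean.

## Selection semantics

* **Thresholds** are inclusive on both bounds: with a maximum of 50 Å of
  accumulated motion, a micrograph at exactly 50 Å is kept and only
  motion *over* 50 Å is discarded. Rows with `NA`/`NaN` in a thresholded
  column are discarded with a warning — the fail-safe reading for
  micrographs whose processing is still in flight.
* **Lasso polygons** must be simple (validated by a segment-intersection
  scan) with nonzero area. Boundary points count as selected: a user who
  circles a point intends to include it. The point test is ray casting
  with an explicit collinearity check for the boundary; the tests compare
  it against an independently written winding-number oracle and against
  `mgcv::in.out`.
* All filters are pure functions returning new tables; "live" filtering
  is re-running the same pure filter on a re-read file (the polling loop
  lives in the CLI). Threshold filtering and lasso selection therefore
  commute, which the suite asserts.
* Re-export writes the optics block (when given) before the data block,
  the layout RELION expects for particle files; block names follow the
  RELION 4 dialect (`data_optics`, `data_particles`,
  `data_micrographs`).

## Pipeline graph

`pipeline.star` describes a bipartite graph — processes (jobs) and data
nodes (files) joined by output edges (job → file) and input edges
(file → job). Job types and statuses are passed through as text, not
enums, so job types introduced by newer RELION versions parse unchanged;
the exact RELION 4 label spellings live in one internal dialect table so a
future rename is a one-line change. The induced job graph (A feeds B
through at least one shared node) must be acyclic; `topological_order()`
is Kahn's algorithm with ties among ready jobs broken by job name, so the
order is a deterministic function of the graph (the reason this is
hand-written rather than delegated to a graph library, none of which
guarantee the tie-break).

## Run tracking

* `discover_iterations()` re-scans `run_itNNN_model/optimiser.star` pairs
  on demand. Live behaviour is polling; there is no filesystem-event
  subscription, keeping the contract portable across filesystems and
  schedulers.
* `extract_series()` looks a label up in the optimiser file's pairs
  first, then the model file's — a documented, deterministic precedence
  for labels present in both.
* `fsc_crossing()` linearly interpolates the first downward crossing of
  the Fourier shell correlation through the threshold and reports
  $1/f_\times$ in Å. The default threshold 0.143 is the gold-standard
  criterion for FSC between independently refined half-maps. A curve
  that never reaches the threshold reports the Nyquist resolution with an
  `at_nyquist` flag rather than extrapolating.
* `angular_histogram()` bins rotation ∈ [−180°, 180°] × tilt ∈ [0°, 180°]
  on a regular grid, 5° bins by default (72 × 36) to match typical
  orientation plots; values on a right/top edge fall in the last bin so
  the particle count is conserved exactly.
* `job_backlog()` defines done = rows of the job's output table and
  pending = upstream rows − done, floored at zero because during live
  polling an output table can momentarily run ahead of a stale input
  listing.

## Previews

MRC reading supports modes 0/1/2 (int8/int16/float32), taking the first
section of a stack and the pixel size from the header cell dimensions;
images are displayed row-major with the origin top-left and no flips
applied. Normalization maps the [1st, 99th] intensity percentiles to
[0, 255] — percentiles rather than min–max because a single hot pixel
would otherwise crush the display range; a constant image maps to
mid-gray 128. Previews are mean-pooled 4× by default to dashboard size,
and rendering is deterministic (re-rendering the same inputs is
byte-identical).

## What the synthetic generator emulates — and what it does not

The generator exists so that every reader in the package has a writer and
every claim a planted ground truth. Its defaults describe a small but
complete session: 10 micrographs of 128 × 128 px at 1 Å/px, ice-ring
amplitudes drawn uniformly from [0, 2], ring at 3.8 Å (inside the
3.6–4.0 Å ice band), unit-variance Gaussian white noise. The test suite
mostly runs it at 64 × 64 px and 2–30 micrographs; those sizes are stated
where used and keep the whole suite under half a minute while leaving
dozens of Fourier samples in the ice band.

The **ice ring** is implemented as a radially symmetric amplitude boost
in Fourier space: the noise field's transform is multiplied by
$1 + a\,\exp\!\bigl(-(f - 1/r_0)^2 / 2\sigma^2\bigr)$ with annulus width
$\sigma = 0.01\ \text{Å}^{-1}$. Boosting the field's own coefficients —
rather than adding an independent ring component — makes band power
*strictly* increasing in the amplitude $a$ at fixed seed (an independent
additive component carries a random cross term against the noise that can
locally invert the ordering at small amplitudes), and amplitude 0 is
exactly the untouched noise field, so the amplitude-0 score *is* the
noise-floor band mean. The avrot fixtures write the micrograph's actual
normalized radial profile as their background-subtracted row, closing the
loop between the two scoring routes.

What the generator deliberately does **not** emulate: particles, CTF
oscillations in the micrographs, detector MTF, amorphous-ice background
shape, or dose-dependent fading. Passing tests therefore demonstrate
that the metadata plumbing, the spectral computations and the score's
ordering behaviour are correct — not that the score separates good from
bad ice on any particular real data set, which depends on microscope and
specimen factors outside the model. Similarly, the planted
classification runs (decaying convergence series, linearly interpolated
class fractions, parametric FSC-like curves) are serialization tests,
not simulations of expectation-maximization behaviour.

Determinism is strict: every generator seeds a private RNG stream and
restores the caller's, so identical specs give byte-identical trees.
Planted class fractions are rounded to six decimals with the last class
set to the complement, so rows sum to 1 within 1e-6 after serialization.

## CLI design

The artifact is a tool, so a thin `exec/relmeta` script exposes
`simulate`, `score-ice`, `filter`, `select`, `graph`, `track` and
`render` over the package functions; all logic lives in testable R
functions and the script is two lines. `--watch` re-runs the filter every
`--interval` seconds (default 10 s, bounded by `--polls` when given) —
polling, because the upstream trigger mechanisms (scheme/scheduler hooks)
are out of scope. A `--port` flag is accepted and stored for a potential
web front end but serves no function here; serving HTTP is explicitly
out of scope. No command mutates files under the project root; all
outputs go to the requested output paths.

## Known limitations

* The STAR dialect omits CIF save frames, semicolon multi-line fields and
  dictionary validation — none of which RELION emits or needs.
* Ice scores are comparable within one acquisition setup; the absolute
  scale depends on pixel size, spectrum normalization and the chosen
  avrot row, so thresholds must be chosen per session.
* The pipeline dialect follows RELION 4 spellings; RELION 5 renames would
  be added to the internal dialect table.
* MRC writing emits mode 2 only; reading a mode other than 0/1/2 raises
  an explicit unsupported-mode error.
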