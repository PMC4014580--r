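---
title: "Methods: rhythm detection and community dynamics in observatory imagery series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection and community dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventrhythms)
```

This vignette documents the statistical procedures implemented in
`ventrhythms`, the assumptions behind them, the defaults of the
synthetic-data generator, and every numerical convention a user might need
to know to reproduce or audit a result.

## The data model

All analyses operate on the `hourly_series` container: one variable on a
regular UTC grid with `NA` marking slots where no usable observation exists
(black-outs, unusable frames). The emulated deployment is a 23-day hourly
recording — 559 slots from 2011-10-07 08:00 to 2011-10-30 14:00 UTC, of
which 23 are missing, leaving 536 usable frames. Gaps are carried through
every computation explicitly; nothing in the package imputes or
interpolates. Counts become densities (ind/m²) by dividing by the filmed
area (0.0355 m² in the emulated design), so results are comparable across
zoom epochs.

## The Whittaker–Robinson periodogram

Folding a series at candidate period $T$ assigns slot $i$ (0-based) to
column $i \bmod T$ of a Buys–Ballot table. The amplitude statistic is the
standard deviation of the column means,
$$B(T) = \mathrm{sd}\{\bar{x}_1, \dots, \bar{x}_T\},$$
scanned over integer $T = 2, \dots, \lfloor n/2\rfloor$ (279 for the full
design). Column means average only observed members; a column with no
observed member is excluded from the statistic. We use the sample ($n-1$)
standard deviation by default; `sd_type = "population"` is available
because other implementations divide by $n$ and the choice is otherwise
arbitrary (it cancels in the permutation test, which compares like with
like).

**Stationarity.** The statistic assumes a stable mean. Series are screened
with an OLS regression of the values on the 0-based slot index and a
two-sided t-test on the slope at $\alpha = 0.05$ (`trend_test()`); a
significant slope triggers linear detrending to residuals
(`detrend()`, `detrend = "auto"` in `wr_periodogram()`). The slot index,
not wall-clock seconds, is the regression abscissa — residuals are
invariant to that scaling. We chose the simplest screen consistent with
removing trends by linear regression; unit-root style tests would be
overkill for a 23-day window.

**Permutation test.** One-sided (large amplitude = periodicity):
$p(T) = (1 + \#\{B^*(T) \ge B(T)\})/(n_{\mathrm{perm}} + 1)$ with 999
permutations by default. Permutations shuffle the observed values over the
observed slots and leave the missing pattern fixed, preserving the
information-loss structure of the gaps. The `+1` convention avoids $p = 0$.
Amplitude comparisons use a relative tolerance of $10^{-8}$ so that
permutations that are exact ties in exact arithmetic (common at small $n$)
are counted as ties rather than split by floating-point summation order.
When an explicit permutation matrix is supplied the set is treated as the
complete null (include the identity) and $p$ is the exact proportion —
this is how the test suite certifies the Monte-Carlo path against
exhaustive enumeration at $n \le 8$.

**Multiplicity.** No correction across periods by default: the
periodogram is read as a profile with per-period $p < 0.05$ marks, and the
harmonic structure (below) makes neighbouring periods strongly dependent
anyway. `correct = "holm"` is available for users who want family-wise
control across the scan.

### Harmonics and the integer-grid drift effect

Two intrinsic properties of the statistic shape how periodograms must be
read, and both are visible in the package's own simulations:

* **Harmonics.** Folding at any integer multiple $kT$ of a true period $T$
  reproduces the periodic profile ($k$ copies per table row), so $B(kT)$
  is as large as $B(T)$ — slightly larger in noise, since longer tables
  have fewer values per column and the noise contribution to the column
  means, $\sigma^2/m$, grows with $T$. A significant comb at 12, 24, 36,
  48 h is one semi-diurnal rhythm, not four independent ones.
  `harmonics()` enumerates the multiples.

* **Drift at non-commensurate periods.** Candidate periods are integers
  (the sampling grid is hourly), but tidal constituents are not: the
  principal lunar semi-diurnal period is 12.42 h. Folding a 12.42-h
  sinusoid at $T = 12$ advances its phase by $0.42/12.42 \approx 0.034$
  cycles per fold; over the full 559-slot design (~46 folds) the column
  means average across ~1.5 cycles of drift and the amplitude collapses to
  roughly 20% of its aligned value (a Dirichlet-kernel attenuation). The
  nearest integer to the *second* harmonic, $2 \times 12.42 = 24.84
  \approx 25$, drifts only ~0.14 cycles over the series and stays
  coherent. A pure 12.42-h forcing on the full grid therefore shows up
  most strongly at 25 h and its multiples, while the reading at 12 h is
  attenuated and crosses the significance threshold only in a minority of
  realisations; shorter windows drift less (a 144-slot series retains
  ~78% of the amplitude at $T = 12$). The acceptance script handles this
  honestly by reporting the *modal* significant in-band period over many
  generator seeds: amplitudes at non-matching periods are conservative
  under the permutation null (the signal variance enters the null but
  concentrates at the coherent periods), so when the sub-20-h band does
  contain a significant period it is essentially always 12.

## Permutation correlations and Holm correction

Associations between taxa and between taxa and environment use the Pearson
coefficient over mutually observed slots with a two-tailed permutation
test (999 permutations): the permutation null supplies distribution-free
inference, so no normality assumption is needed while retaining the
familiar linear-association measure. The number of complete pairs actually
used (`n_used`) is always reported. Coarser sampling frequencies (4-, 6-,
12-hourly) are obtained by `subsample()` — every $k$-th slot, timestamps
preserved, never interpolated; with 559 hourly slots the 12-hourly grid
has 47 slots, and 45 usable values when two retained slots are missing.
The Holm correction is applied within the family of all pairs at one
frequency; the family boundary is configurable because any choice here is
a convention, and per-frequency families match how the tests are read
(each frequency is a separate screen of the same hypotheses at lower
power).

## Nearest-neighbour segregation

Each hourly frame is an independent point pattern of pixel-annotated
individuals. Within a frame, every individual's Euclidean nearest
neighbour is found (ties broken deterministically by lowest record index —
pixel-quantised coordinates do produce exact ties) and
$N_{AB}$ counts individuals of taxon $A$ whose neighbour is of taxon $B$;
rows conserve abundances. Under random labelling of the fixed locations
the expectations are $E_{AA} = n_A(n_A-1)/(N-1)$ and
$E_{AB} = n_A n_B/(N-1)$. Dixon's segregation index is the log odds
ratio
$$S_{AA} = \ln\frac{N_{AA}/(n_A - N_{AA})}{(n_A - 1)/(N - n_A)}, \qquad
  S_{AB} = \ln\frac{N_{AB}/(n_A - N_{AB})}{n_B/(N - 1 - n_B)},$$
with degenerate (zero or full) counts reported as $\pm\infty$ and flagged
rather than hidden. For the multi-frame analysis, observed and expected
counts are computed per frame and summed, and $S$ is formed from the
pooled observed and pooled expected odds; with a single frame this reduces
algebraically to the per-frame formula. (Whether a published multi-frame
table was pooled this way or some other way is generally not recoverable
from the table itself; the pooling rule here is stated so results are
auditable.) Significance is by label permutation within frames only —
the asymptotic z-tests of the original framework are out of scope.

Heat maps bin the same annotations into square bins of side
$\lceil\sqrt{A_{bin}/A_{pixel}}\rceil$ pixels (nominal bin area 1.125 cm²
in the emulated design), tiling from the top-left origin, left-closed on
both axes; counts are conserved by construction and the realised bin area
is reported, since the nominal area rarely divides the frame exactly.

## Variation partitioning

The response is the multi-taxon density matrix (visiting taxa with
near-all-zero counts are excluded by default — they carry no usable
variance); predictors are two sets: temperature probes ($X$) and temporal
eigenfunctions ($W$).

**Temporal eigenfunctions** are distance-based Moran eigenvector maps
(dbMEM) on the one-dimensional time axis: Euclidean temporal distances,
truncation at the largest gap between adjacent retained slots (the
smallest threshold that keeps the design connected), distances beyond the
threshold replaced by four times it, principal-coordinate decomposition of
the centred transformed matrix, positive-eigenvalue axes retained. dbMEM
is the standard construction for "temporal eigenfunctions" in the
variation-partitioning literature; on a complete regular grid the axes are
discrete sinusoids ordered from the whole-window scale down to the
sampling step, so they form a flexible periodic basis. The basis is
returned orthonormal; scaling is irrelevant for regression use.

**Fractions.** With $R^2_{adj}$ the Ezekiel-adjusted canonical R²
($1 - (1-R^2)(n-1)/(n-m-1)$, unbiased under the null), the partition is
$[a] = R^2_{abc} - R^2_{bc}$, $[c] = R^2_{abc} - R^2_{ab}$,
$[b] = R^2_{ab} + R^2_{bc} - R^2_{abc}$, $[d] = 1 - R^2_{abc}$.
Slightly negative fractions are an expected artefact of the adjustment and
are reported unclipped (with a warning), never truncated to zero. The
testable fractions ($[a{+}b]$, $[b{+}c]$, $[a{+}b{+}c]$, $[a]$, $[c]$)
receive residual-permutation (Freedman–Lane) p-values; $[b]$ is not a
testable hypothesis under standard theory — it is a difference of R²
statistics with no associated model — so it is deliberately reported
without a p-value, and $[d]$ likewise. The implementation is cross-checked
in the test suite against an independent variation-partitioning
implementation (`vegan::varpart`) to $10^{-8}$, and the identities
$a+b = [a{+}b]$, $a+b+c+d = 1$ are asserted to $10^{-10}$.

**Forward selection** uses the double stopping criterion: candidates enter
greedily by largest partial R² contribution, each tested by residual
permutation at $\alpha = 0.05$, and selection stops once the cumulative
adjusted R² reaches that of the all-candidates model (the guard against
accumulating spurious predictors). One convention deserves note: the
candidate that crosses the cap is *kept* if it passed the significance
test, and the scan stops after it. The cap exists to stop noise
accumulation, and with strong predictors the last true one routinely lands
within sampling noise of the cap; rejecting it would make recovery of a
planted model a coin flip, which the recovery simulations in the test
suite (planted 3-of-20 designs at $n = 500$) would flag immediately.
Under a pure-noise null the $\alpha$ rule stops first, so the convention
does not inflate selection.

Rows with any missing value in the response or predictors are dropped
(complete-case alignment of the usable frames with the probe records);
`n` in the result is the row count actually used.

## Frame-quality metrics

Percent microbial cover is the white fraction of a binary annotation mask
(greyscale inputs are thresholded at the midpoint of their nominal scale,
with a message). The luminosity index converts each pixel to hue,
saturation and lightness scaled 0–255. How the three channels combine
into one index is a design choice with no canonical answer; the default
(`mode = "lightness"`) averages lightness only, so the endpoints behave
exactly as a luminosity index should — an all-black frame scores 0 and an
all-white frame 255. The alternative `mode = "mean-hsl"` averages all
three channels (an all-black frame then scores ≤ 85 because hue and
saturation are zero but still enter the mean). Both modes are strictly
increasing in uniform lightness changes, which is the property that
matters for tracking the progressive darkening of a long recording.

## The synthetic-data generator

The generator exists so that every downstream stage is testable with no
deposited data; its defaults *are* the emulated study conditions, chosen
once and not revisited:

* **Grid**: 559 hourly slots from 2011-10-07 08:00 UTC, 23 missing slots
  drawn uniformly without replacement. The true gap positions of the
  deployment are unpublished, so uniform placement is the neutral choice,
  and a chi-square goodness-of-fit test over many seeds confirms
  uniformity in the suite.
* **Signal**: base level + linear trend + sinusoids (tidal forcing at
  12.42 h and 24.84 h) with phases drawn uniformly on $[0, 2\pi)$ per
  component, plus AR(1) noise initialised at its stationary variance
  $\sigma^2/(1-\phi^2)$.
* **Families**: Gaussian for sensor-like series; Poisson counts with
  latent mean clamped at zero for faunal counts (densities are
  nonnegative counts per area).
* **Levels** (`simulate_study()`): per-frame abundances of ~30 tubeworms,
  ~6 polynoids, ~20 pycnogonids, ~3 buccinids and a 4% zoarcid presence
  rate match the order of magnitude of the emulated assemblage; probe
  base temperatures (2.5–10.9 °C) span the deployed thermistors, with one
  probe nearly arrhythmic and probe-specific tidal amplitudes of a few
  tenths of a degree; mild drifts trigger the stationarity screen in some
  probes, exercising the auto-detrend path.
* **Point patterns**: per-taxon cluster centres drawn once per seed
  (stable "home ranges" shared across frames) with isotropic Gaussian
  spread, rejection-sampled to stay inside the frame; exact per-taxon
  counts.
* **Determinism**: identical spec + seed give byte-identical output; the
  RNG draw order (phases, noise, counts, missing slots) is fixed, and the
  caller's RNG state is restored afterwards.

What the generator does **not** emulate: behavioural bout structure and
zero inflation beyond Poisson, the non-sinusoidal shape of real tidal
forcing and its multi-constituent mixture, cross-taxon dependence beyond
shared forcing, observation error in the annotations, and the per-epoch
zoom changes of a real deployment. Passing tests therefore certify the
statistical machinery under the stated generative assumptions — they do
not certify that real vent fauna behave like the generator.

## Problem sizes and runtime choices

The test suite runs calibration checks at reduced sizes chosen to keep the
full suite under a minute while leaving the statistical behaviour
measurable: type-I calibration of the periodogram on 100 null series of
40–48 slots with 99 permutations; exhaustive permutation checks at
$n \le 8$ (40 320 permutations); recovery of an injected integer-grid
period over 100 seeds of the full 559-slot design with 99 permutations;
forward-selection and fraction-recovery simulations at $n = 500$–536. The
acceptance script uses the full design (559 slots, 999 permutations, 31
seeds per reading). The periodogram's permutation scan is vectorised (all
permutations folded simultaneously per candidate period), so a full
559-slot, 999-permutation scan over periods 2–279 takes well under two
seconds; its amplitudes are asserted equal to the scalar
`fold()`/`wr_statistic()` path in the suite.

## Known limitations

* Integer candidate periods only: non-commensurate rhythms are read via
  the drift/harmonic structure described above rather than estimated as
  real-valued periods; no Lomb–Scargle or harmonic regression is
  provided.
* Dixon's asymptotic z-tests for the segregation counts are not
  implemented; inference is by label permutation.
* The per-frame filmed area is a single scalar; per-epoch area tables
  (zoom changes) must be handled by splitting the series before
  conversion.
* Forward selection is greedy; with strongly collinear candidate sets
  (neighbouring dbMEM axes are orthogonal, but temperature probes are
  not) the selected labels are one representative of several nearly
  equivalent subsets.
* Fractions from variation partitioning are adjusted-R² differences;
  with very few complete-case rows they can be materially negative, and
  they are reported as such.
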