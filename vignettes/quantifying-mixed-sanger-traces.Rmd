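---
title: "Quantifying two-variant DNA mixtures from Sanger electropherograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-variant DNA mixtures from Sanger electropherograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsanger)
```

## The model

A Sanger electropherogram is a four-channel amplitude series `b_i(t)`
(`i ∈ {G, A, T, C}`), one channel per dye-labelled terminator base, together
with the sample index `t_K` of each called base's peak. When the template is
a pool of two variants P1 and P2 at fractions `ω` and `1 − ω`, the two
variants are amplified in the same reaction, so — to a good approximation —
the mixed trace is a convex combination of the traces the two pure templates
would produce *in that same run*:

```
b^M(t) ≈ ω · s^P1(t) + (1 − ω) · s^P2(t)
```

The catch is that the pure-variant traces we can actually measure come from
*different* runs: fragments migrate at run-specific speeds (a monotone time
distortion) and overall signal level and decay differ between reactions.
`qsanger` therefore estimates `ω` in three steps: register the three reads
at *anchor points*, warp the reference traces into the mixed read's time
frame, and solve a one-parameter least-squares problem at the positions
where the references diverge.

An anchor point is an aligned, gap-free position where (i) both references
call the same base, (ii) both reference traces are pure there — the
second-largest channel is below 2.8% of the summed column amplitude — and
(iii) the mixed read shows a single peak. At such positions all three
traces carry the same lone peak, so their peak times register the time axes
and their amplitude ratios register the gains. Between consecutive anchors
the reference time axis is stretched linearly (`timeStretch()`), and the
per-time gains `λ1(t)`, `λ2(t)` interpolate the anchor amplitude ratios
linearly (`amplitudeScale()`). Warping is exact at anchors by construction.

The estimate itself minimizes

```
e(ω) = Σ_t ( b^M(t) − ω λ1(t) b̄^P1(t) − (1 − ω) λ2(t) b̄^P2(t) )²
```

over `ω ∈ [0, 1]`, where `b̄` denotes a warped reference. The objective is
an exact quadratic in `ω`; writing `f1 = λ1 b̄^P1`, `f2 = λ2 b̄^P2`, the
normal equation gives the closed form

```
ω* = Σ (b^M − f2)(f1 − f2) / Σ (f1 − f2)²
```

clamped to `[0, 1]` afterwards. The test suite verifies the closed form
against an independent grid-plus-refinement numeric minimizer to 1e-6 on
random instances; the reported residual is the objective at the clamped
optimum.

### Assumptions

* exactly two components — three-or-more-variant deconvolution is out of
  scope;
* the variant sequences align without indels over the analysed window
  (substitution divergence only);
* enough identical, pure positions exist to anchor the registration (at
  least 5, by default);
* at least one divergent position falls inside the quality window —
  otherwise quantification is refused (`"sequences do not diverge in
  window"`) rather than reporting a meaningless number.

## Tunable parameters

All pipeline constants live in `qsangerConfig()`, never in the stage
functions:

| parameter | default | meaning |
|---|---|---|
| `relThreshold` | 0.014 | minimum fraction of the summed column amplitude for a secondary peak in the mixed read |
| `absThreshold` | 50 | absolute amplitude floor (fluorescence units) for a secondary peak, suppressing baseline flicker |
| `purityThreshold` | 0.028 | secondary fraction above which a reference position cannot anchor |
| `trimFirst`, `trimLast` | 20, 1000 | retained base-call window of each read (leading bases are low quality/uninformative, quality decays past 1,000) |
| `windowStart`, `windowEnd` | 20, 600 | post-trim base positions whose divergent columns enter the fit (the highest-quality stretch of a capillary read) |
| `minAnchors` | 5 | fewer anchors is a hard failure |
| `gapPenalty` | −2 | per-position gap score in the global alignment |
| `doubleGapScore` | −1 | mixed base aligned to gaps in both references |
| `integration` | `"informative"` | objective support (see below) |

The secondary-peak rule uses `≥` on both thresholds: a peak at exactly
1.4% of the column sum, or at exactly amplitude 50, is called. The purity
rule uses strict `<`: a secondary channel at exactly 2.8% disqualifies the
anchor. The boundary tests pin this orientation down.

## Design choices where the design was open

**Support of the objective.** The integral bounds of the objective span the
whole quality window, yet only divergent positions carry contrast — summing
over identical regions would add noise to both sides of the model without
information. The default (`integration = "informative"`) therefore sums
over samples within half a peak spacing of each informative column's peak,
on the two divergent bases' channels only. `integration = "full"`
integrates over the whole window on all four channels; on clean synthetic
data both agree, and the tests assert it.

**Which columns are informative.** A divergent column is used whenever
every mixed peak at that position belongs to the reference pair `{p1, p2}`.
This includes *single-peak* divergent columns: near `ω = 0` or `ω = 1` the
minor component legitimately falls below the secondary-peak thresholds, and
those columns are exactly what pins the estimate to the boundary. A column
where some mixed peak matches neither reference is a mismatch — counted,
reported, never fitted.

**Window coordinates.** The quality window 20–600 is applied to post-trim
base positions (the coordinates the alignment works in). Trimming already
removes the first 20 calls of the raw read, so the fitted region sits
wholly inside the trimmed span; the window must lie inside the trimmed read
and `qsangerConfig()` enforces that.

**Gain definition.** Gains are computed from the anchor base's channel
only. Anchors are single-peak by construction, so the other three channels
carry mostly baseline there and their ratios would be dominated by noise.
By symmetry the second reference's gain is the mixed amplitude over the
warped P2 amplitude — the mirror image of the P1 gain.

**Pairwise projection of the column score.** The three-way column score
cannot drive a pairwise aligner directly (its most informative case — a
single peak resolving two *divergent* references — needs both references at
once). Each pairwise alignment therefore uses the single-reference
projection (match 1, reference base within a two-peak pair 0.85, mismatch
0, gap −2), and the full three-way score including the 2 and 0.75 cases is
recomputed on the merged columns, with −1 for a mixed base aligned to gaps
in both references. An exhaustive-recursion oracle checks the aligner on
short pairs.

**Monotonicity repair.** Alignment can emit anchor candidates whose peak
times regress in one frame (e.g. around compressions). Candidates breaking
strict increase in any of the three frames are dropped greedily, keeping
the earlier anchor, because the piecewise-linear warp needs monotone
segments. The repair is deterministic.

**Tie-breaks and degenerate inputs.** Equal channel amplitudes resolve in
fixed order G, A, T, C, making peak calling deterministic. An all-zero
column is treated as pure but is never used as an anchor (its gain would be
0/0). Anchors with a zero warped-reference amplitude are skipped and the
gain interpolation bridges to the next usable anchor; if *no* anchor is
usable the run fails loudly. A zero contrast denominator (`f1 ≡ f2` on the
support) raises `"degenerate contrast"` instead of dividing by zero. The
closed-form/numeric-oracle agreement is asserted at 1e-6; exact-limit
recovery at 1e-3.

## The synthetic-trace generator

`simSpec()` / `simulateTrace()` emulate an analyzed capillary trace: each
base contributes a Gaussian peak (sd 2.4 samples) on its channel at ~12
samples per base with per-base spacing jitter (sd 0.25), amplitudes start
at 5000 units and decay exponentially at 5e-4 per base (~40% over 1,000
bases), an optional monotone piecewise-linear warp distorts the time axis
per run, a 4×4 crosstalk matrix leaks signal between channels, and
truncated Gaussian noise (default sd 50, i.e. 1% of the initial amplitude)
is added per sample. These values are typical of analyzed ABI traces and
give well-resolved peaks (spacing > 4 sd).

`simulateMixture()` builds the mixed read the way the chemistry does: both
variants share one run's peak layout and warp, and the pre-noise signal is
the exact convex combination of the two pure signals — an invariant the
tests assert. Reference reads are independent runs with their own seeds,
jitter, warps and noise.

What the generator does *not* model: dye-dependent mobility shifts,
base-specific peak-shape asymmetries, indel-induced frame shifts after a
heterozygous gap, quality-score traces, and heavy-tailed instrument
artifacts. Passing the synthetic recovery suites therefore demonstrates
the correctness of the registration and estimation machinery under the
stated trace model, not instrument-level robustness; on real AB1 data the
anchor purity and secondary-peak thresholds do the work of rejecting
positions the model does not fit.

## Problem sizes used by the test and acceptance suites

The calibration twin simulates 420-base templates diverging at 25
positions, quantified at ratios 0, 0.1, 0.3, 0.5, 0.7, 0.9, 1 with three
replicates (21 end-to-end runs, independent mild warps, 1% noise) and
regresses estimate on truth; `scripts/acceptance.R` reports its R².
Unit fixtures use 6–300-base reads so each stage's oracle (exhaustive
alignment recursion, analytic resampling, numeric minimizer) stays cheap.
These sizes were chosen to exercise every code path at interactive speed;
the pipeline itself handles full 1,000-base reads.

## Known limitations

* Two components only; no confidence interval on `ω` is provided (the
  residual and per-column estimates in `diagnostics` are the available
  dispersion diagnostics).
* Indel-divergent variant pairs are not simulated (the aligner itself
  handles gaps, but mixed traces downstream of a heterozygous indel are
  frame-shifted superpositions the two-peak model does not describe).
* The least-squares objective implicitly weights positions by amplitude;
  early high-amplitude positions influence `ω` more than late ones. The
  per-column estimates let a user check for position effects.
* The ABIF writer emits the minimal tag subset the reader consumes; it is
  a serialization format for this package, not a general AB1 authoring
  tool.
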