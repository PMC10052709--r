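---
title: "Methods: slice-decimated CT hepatic volumetry on a synthetic canine cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-decimated CT hepatic volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepavol)
```

## The estimators

Slice-summation volumetry rests on the Cavalieri principle: the volume of a
solid equals the integral of its cross-sectional areas along an axis. With
transverse CT slices of thickness $t$ (cm) and traced liver areas $A_i$
(cm$^2$) on the $N$ liver-bearing slices, the full reference volume is

$$V = t \sum_{i=1}^{N} A_i .$$

When only every $k$-th slice is traced (slice interval $= k\,t$), the
extrapolated estimator rescales the subset sum by the fraction of slices
used:

$$\hat V_p = t \sum_{i \in S_p} A_i \times \frac{N}{|S_p|},
\qquad S_p = \{\,p+1,\ p+1+k,\ \dots\,\} \subseteq \{1,\dots,N\},$$

one estimate per phase offset $p = 0,\dots,k-1$. The $k$ subsets partition
the slices, and two identities anchor the implementation (both are asserted
as tests): the estimator is exact for constant-area profiles for *every*
subset, and when $k \mid N$ the arithmetic mean of the $k$ phase estimates
equals $V$ exactly, because each slice then appears in exactly one subset
with the same weight $N/|S_p| = k$.

For $k \nmid N$ the phases have unequal sizes $|S_p| = \lceil (N-p)/k
\rceil$ and the estimator uses the *actual* subset size, which keeps every
phase unbiased in the constant-profile case. Internally subsets are 1-based
R index vectors while the phase label stays $0,\dots,k-1$; phase $p$ starts
at slice $p+1$.

Accuracy is measured per measurement as the percent difference from the
*same subject and observer's* full volume, $|\hat V - V|/V \times 100$ —
matching decimated to full tracings within an observer is the only pairing
that makes the design's measurement accounting (192 rows per observer, 576
in total for the default 16-subject, 3-observer cohort) internally
consistent.

Interobserver agreement of the full volumes uses three statistics per
subject: the coefficient of variation $\mathrm{CV} = s/\bar V \times 100$,
the greatest percent difference $(\max - \min)/\bar V \times 100$ with
$\bar V$ the mean over *all* observers, and a symmetric pairwise percent
difference $|a-b| / \frac{a+b}{2} \times 100$. Two of these involved open
choices: whether the SD in the CV uses $n$ or $n-1$ is not derivable from
the study description, and we use the sample ($n-1$) SD as is conventional
for a three-observer sample; and the pairwise denominator is likewise
unstated, so we chose the pair mean for symmetry. For two values the
greatest percent difference and the pairwise statistic coincide by
construction.

## Study design

The default `study_design()` runs, at 2.5 mm thickness, the intervals 5,
7.5, 10 and 15 mm ($k = 2,3,4,6$) and, at 3.75 mm, the intervals 7.5, 11.25
and 15 mm ($k = 2,3,4$), each against its own full group. Group summaries
report mean and sample SD of the percent difference, pooled across
observers and also split by observer (whether published per-group scatter
pools observers is ambiguous, so both tables are emitted). Per-interval
worst cases pool the groups that share an interval (7.5 mm pools the 2.5 mm
and 3.75 mm cohorts, as does 15 mm).

Slice-count bins summarise the worst case by the number of slices actually
used: fewer than 10, 10–14, 15–19, 20–24, and 25 or more. Read literally,
the source bin wording ("20 to 24", "more than 25") leaves $n = 25$
unassigned; we define the last bin as $\ge 25$ so the bins form a
contiguous partition of the positive integers. Empty bins are reported with
$n = 0$ and no maximum.

## The phantom generator

No canine CT series are distributed with the package, so all statistical
claims are exercised on a synthetic cohort that reproduces the design
constants: 8 subjects per thickness at 2.5 and 3.75 mm, three observers,
and liver spans of 36–63 slices (drawn uniformly, independent of
thickness).

**Area profiles.** The per-subject profile is a scaled Beta-density curve
over the slice axis: at slice midpoint $x_i = (i - \tfrac12)/N$ the area is
proportional to $(1-\epsilon)\,\mathrm{Beta}(x_i;\, 1+ps,\ 1+(1-p)s) +
\epsilon$, with peak position $p \sim U(0.35, 0.6)$, sharpness $s \sim
U(3, 8)$ and a uniform floor $\epsilon = 0.05$. This family was chosen
because it is smooth, strictly positive, unimodal (constant in the
degenerate limit $s = 0$, which the tests exploit), and trivially
rescalable to hit a target volume exactly; the floor keeps the cranial and
caudal tip slices at a realistic few cm$^2$ instead of tapering towards
zero (it also guarantees that rasterisation at the default 1 mm pitch is
feasible). No anatomical liver shape model is implied.

**Volumes.** Only two cohort moments of the real volumes are known (mean
722.2, SD 281.2 cm$^3$), so full volumes are drawn uniformly on
$[236, 1208]$ cm$^3$, which reproduces exactly those two moments (uniform
mean $722$, SD $972/\sqrt{12} \approx 281$). Phantom realism beyond these
moments and the slice-count range is not claimed.

**Observer noise.** Each observer multiplies every area by
$\exp(b + \varepsilon_i)$, with one systematic draw $b \sim N(0,
\sigma_b)$ per observer per subject and independent per-slice jitter
$\varepsilon_i \sim N(0, \sigma_s)$. Multiplicative lognormal noise was
chosen because tracing errors scale with the boundary, and it keeps areas
strictly positive. $\sigma_s = 0.05$ (5% per-slice) was fixed a priori as a
plausible manual-tracing jitter; at the whole-volume level it averages out
to under 1%. $\sigma_b$ dominates the interobserver CV and is set by
`calibrate_observer_noise()`, which pre-draws profiles and unit normals
once (common random numbers) and solves for the $\sigma_b$ whose cohort
mean CV equals the 2.5% target with `uniroot()`; the resulting value,
0.0271, is frozen as the package default. Zero noise is the identity on
areas, which downstream tests use to assert that all statistics vanish.

**Random streams.** One root seed generates per-subject sub-seeds
(subject-major order); each subject's stream first produces the profile and
then the per-observer seeds, so enlarging the observer panel never
perturbs the subject profiles, and identical specifications give
bit-identical cohorts.

**What the phantom does not emulate.** Real tracing error is spatially
correlated along the boundary and between adjacent slices, livers have
lobes, fissures and excluded vessels, and slice count covaries with dog
size and slice thickness. Decimation error on the phantom therefore comes
almost entirely from the observer-noise roughness of otherwise smooth
profiles, and its worst cases are milder than clinical ones at small slice
counts. Passing tests show that the estimators, accounting and statistical
machinery are correct and that the calibrated noise level reproduces the
qualitative structure (error growing with interval, worst cases shrinking
with slice count, sub-5% behaviour at $\ge 20$ slices); they do not certify
clinical error magnitudes in the sparsest bins.

## Numerical choices and degenerate inputs

* Volumes are carried in cm$^3$ at full double precision; rounding to one
  decimal happens only in presentation columns and printed summaries.
* Thickness/interval compatibility and scheme-series matching use an
  absolute tolerance of $10^{-8}$ cm; the decimation factor must be an
  exact integer multiple within that tolerance.
* A series must have strictly positive first and last areas (it covers
  exactly the liver-bearing slices); interior zero areas are tolerated with
  a warning at mask-extraction time, since whether real livers ever show
  interior zero-area slices is unknown.
* Mask extraction converts foreground-pixel counts with the header spacing
  (mm$^2 \to$ cm$^2$); rasterisation draws filled discs with
  pixel-centre-in-disc membership, which keeps the pixel-counted area
  within a perimeter row of pixels (and in practice within 1% for the
  default 1 mm pitch) and round-trips volumes within 1%.
* `calibrate_observer_noise()` needs the per-slice noise alone to produce a
  mean CV *below* the target, otherwise it fails with an explicit message
  rather than returning a zero bias.

## Problem sizes

The test suite runs entirely on generated data: property tests use dozens
of random series with up to ~80 slices; calibration checks average 6–8
cohort replicates; the statistical trend checks (error vs interval, bin
maxima vs slice count) average 25 and 100 full cohort-plus-study
replicates respectively, each replicate being the default 48-series cohort
with 576 measurements. These sizes give Monte-Carlo standard errors well
inside the asserted tolerances.

## Limitations

Beyond the phantom caveats above: the package does not interpolate between
slices or reconstruct surfaces (the estimators are exactly the two formulas
given), does not model partial-volume effects or Hounsfield values, and the
interobserver machinery targets a complete subjects x observers design —
incomplete cohorts fail loudly rather than being imputed.
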