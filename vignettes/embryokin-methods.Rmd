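---
title: "Models and methods behind embryokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind embryokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryokin)
```

embryokin quantifies early *Drosophila* embryogenesis from end-on
(dorsal–ventral plane) Histone-GFP time-lapse imaging of embryos held in a
microfluidic trap array, and models the oxygen dynamics of that device during
anoxic perfusion. This vignette explains the models the package implements,
the assumptions behind them, the tunable parameters, and the numerical
choices — in enough detail that a reader can judge what a passing test suite
does and does not demonstrate.

## The nuclear-area signal

During syncytial stages 4–5, peripheral nuclei divide synchronously (nuclear
cycles NC10–NC13), then cellularize over roughly an hour (stage 5) before
ventral furrow formation (VFF) starts gastrulation. Chromatin condensation
makes the *mean nuclear area* of a segmented frame an oscillating clock:
round interphase nuclei give the maxima; nuclei condensing through prophase
and metaphase shrink the mean; maximally compact telophase chromatin gives
the minima. Consecutive minima therefore measure telophase-to-telophase cycle
durations, and the minimum between NC12 and NC13 (nuclear division 12, ND12)
is a convenient anchor for aligning embryos that entered the device at
slightly different ages.

## Segmentation (`relative_difference_filter`, `segment_nuclei`)

Each frame is normalised against its own smooth local baseline,
$F = (I - B)/(B + \varepsilon)$, with $B$ a Gaussian blur of the frame at a
scale larger than a nucleus diameter (default 25 px) and $\varepsilon$ set to
1% of the frame median. Because $B$ and $\varepsilon$ both scale with the
illumination, $F$ is invariant under global gain changes — the property the
test suite checks by multiplying frames by 0.2–5 and requiring identical
label matrices. Nuclei are then the connected components of $F$ above an
automatic bimodal (Otsu) threshold, with components smaller than a 2-µm
circle discarded and an optional distance-transform watershed to split
touching nuclei. A frame whose filtered dynamic range is indistinguishable
from its pixel-noise floor (less than 10 robust scale units, and never less
than 0.2 relative units) is declared empty rather than segmented into noise.
Empty frames yield *missing* mean areas, never zeros, so segmentation
dropouts cannot masquerade as telophase minima.

## Cycle annotation (`detect_minima`, `annotate_cycles`)

Interior missing values are bridged by linear interpolation; the trace is
smoothed with a 3-frame moving average; local minima are kept when their
prominence reaches 10% of the smoothed dynamic range, ties resolving to the
earliest frame; each minimum is then re-localised on the raw trace within one
frame, because the moving average blurs the sharp telophase floor.

Minima are only accepted as divisions if they are followed by chromatin
re-expansion — a raw rise of at least 25% of the dynamic range within
6 minutes. Without this check, a noise dip in the dim post-furrow tail can
pass the prominence filter and, being last in the trace, would corrupt the
backward labelling described next.

Cycles are labelled *backward* from the terminal span after the last
confirmed division: recordings begin at variable pre-stage-4 ages, so
counting forward from recording start is unreliable, whereas the stage-5
plateau is unmistakable. The four inter-minimum intervals preceding it are
NC13, NC12, NC11, NC10. ND9 — the start of NC10 — is usually not an interior
minimum because nuclei arrive at the periphery already in telophase of
division 9; the first valid frame is used as ND9 when its area sits within
25% of the telophase level, and NC10 is reported missing otherwise.

Stage 5 ends at the onset of the terminal decline, the package's VFF proxy:
the detector finds the first sustained (3-frame) excursion below the midpoint
between the stage-5 plateau and the terminal level, then backtracks on the
*raw* trace to the first frame that left the plateau band (3 robust noise
units). A collapse towards zero signal is not a furrow — the terminal level
must stay above 15% of the plateau — which is how delaminating
(failed-recovery) embryos are excluded. Cohort curves are pointwise means
with S.E.M. $= s/\sqrt{n}$ over the embryos contributing at each
ND12-aligned timepoint; per-cycle duration statistics pool the embryos in
which that cycle was annotated, so $n$ can differ between cycles.

## Anoxia arrest and recovery (`detect_arrest`, `recovery_time`)

Under anoxia, nuclei proceed to metaphase, hypercondense, and hold; they
release to anaphase several minutes after normoxia returns. The arrest
detector looks for the maximal run of frames at or below the telophase-level
band (the median area at the detected minima, plus 10%) that overlaps the
anoxia window and lasts longer than 3 minutes — safely above the 1–2 minute
normal metaphase residence and safely below the ≥ 18-minute arrested
plateau, so the margin on both sides is wide. Anaphase onset is defined as
the end of the hypercondensed plateau: the first sustained departure of the
trace from the plateau band after the window closes. For these band
computations a running median (k = 3) replaces the moving average — a median
does not smear a plateau edge backwards in time, which would otherwise bias
the recovery estimate by a full frame. Event times carry a half-frame
midpoint correction so they are unbiased on the sampling grid; recovery time
depends only on times and *relative* levels, hence is invariant to rescaling
the area axis.

Group comparisons use Welch's unequal-variance two-sided t-test per
milestone and per cycle duration, reported treated-minus-control, without
multiplicity correction (raw per-metric p-values). When both groups have
zero variance and equal means, p is defined as 1.

## The synthetic generator as the study condition

No imaging data are distributed with the package, so every quantitative
claim is exercised on synthetic cohorts whose generator encodes the observed
biology; its defaults *are* the study conditions and are not tuned per test.

*Waveform.* Piecewise linear per cycle: a one-frame telophase floor, a rise
to the interphase plateau (20% of the cycle), the plateau, a prophase
decline (30% of the cycle) to a metaphase shoulder at 25% of the
interphase–telophase range, and a 1.5-minute metaphase hold descending to
the next telophase floor. Piecewise linearity preserves the position of the
minima, which is all the kinetics pipeline consumes.

*Defaults.* Cycle durations 7.8, 9.9, 11.4, 16.9 and 59.3 min (NC10–NC13,
stage 5); 60-s frames; 180-min recordings; nuclei first appear 25 min into
the recording; nucleus counts double exactly at each division from 8 at
NC10. The absolute area scale is a free parameter (28 µm² interphase, 8 µm²
telophase); nothing downstream depends on it, as the rescaling-invariance
tests confirm. Additive area noise defaults to 2% of the interphase area —
the per-frame signal is a mean over on the order of a hundred nuclei, so
per-frame noise is small. Embryo-to-embryo variability is a 5% multiplicative
log-normal jitter applied independently to each duration (mean-one
parameterisation), which reproduces cohort S.E.M.s of the observed order
(e.g. ≈ 0.1 min for NC12 at n = 35).

*Anoxia.* The pulse is a 10-minute window on the experiment clock, opening
by default 10.1 minutes after nominal ND12 (mid-NC13, when such experiments
are scored); release to anaphase follows reoxygenation by 7.9 ± 2.6 min
(per-embryo, truncated at zero). The arrested plateau sits at 0.8× the
telophase area (hypercondensation), and release passes through a pronounced
two-frame anaphase/telophase dip at 0.3× the telophase area before
interphase-14 expansion. That dip is deliberate: prolonged arrest leaves
chromatin maximally condensed at release, and it gives the arrested cycle a
well-defined terminal minimum — with a *flat* sub-telophase plateau the
minimum-to-minimum estimate of the arrested cycle would land anywhere in the
plateau under noise and the observed 28.0 ± 0.6 min arrested NC13 could not
be recovered by any minima-based method. With these defaults the arrested
NC13 is 10.1 + 10 + 7.9 = 28.0 min in expectation, i.e. an 11.1-min
extension.

*Recovery overhead.* Recovered embryos additionally delay stage 5 by a
normally distributed overhead (mean 3, s.d. 12 min): observed ventral-furrow
delays exceed the cycle-13 extension by a few minutes on average with a very
large embryo-to-embryo spread, while stage-5 durations remain statistically
indistinguishable between arms. The generator reproduces all three observed
facts at once; with the overhead disabled the VFF delay equals the arrest
extension exactly (the additivity property the tests assert).

*Failure phenotype.* With probability 5/14 the embryo does not recover:
daughter nuclei fuse after the anaphase attempt (the release dip still
occurs, so the arrested-cycle duration and the recovery time remain
measurable, matching how those quantities are reported for all treated
embryos), the count never doubles, and nuclei delaminate — counts collapse
to zero and the signal fades to background. No furrow is ever detected for
these embryos.

*Stacks.* Image stacks place the nuclei as non-overlapping spots on an
annulus (alternating inner/outer stagger so 128 stage-5 nuclei fit), over a
background offset with optional Poisson shot noise, 16-bit. Spots are
flat-top disks with a one-pixel antialiased edge whose half-maximum contour
has exactly the target area. A Gaussian profile was rejected deliberately:
for a Gaussian, thresholded area varies as $2\pi\sigma^2 \ln(1/f)$ with the
threshold fraction $f$, so the measured area would depend strongly on where
the automatic threshold lands; the flat-top profile decouples the two, which
is what makes the trace/stack consistency contract (segmented trace within
5% MAE of the generating trace) meaningful. Divisions re-layout the annulus
(nuclei are not tracked across frames — the features are per-frame
aggregates); furrow formation moves the ventral arc inward; fusion renders
converging daughter pairs.

*What the generator does not emulate* — and hence what passing tests do not
show about real data: z-drift and focus loss, photobleaching, mitotic waves
across the field (divisions are instantaneous at the 1-min sampling),
nucleus-size heterogeneity within a frame, chorion autofluorescence, and
partially overlapping nuclei at high density. The segmentation and kinetics
machinery is exercised against idealised imaging; on real stacks the
watershed split and the baseline scale would be the first parameters to
revisit.

## Oxygen transport model (`simulate_oxygen`)

A 2D transient convection–diffusion model of a device cross-section: a
500-µm gas channel (the serpentine unrolled to its stretched-out length,
40 mm for the small array, 550 mm for the large one) under a 5-mm PDMS slab.
Oxygen diffuses in both layers ($D = 10^{-5}$ m²/s in nitrogen,
$3.55\times10^{-9}$ m²/s in PDMS), advects with the laminar flow in the gas
layer (plane-Poiseuille profile normalised to the 0.285 m/s mean), and
partitions 10:1 (gas:PDMS) at the interface. Initial condition 21%
everywhere; 0% at the gas inlet; 21% ambient on the outer PDMS surface; no
flux through the glass floor; ten minutes simulated with one-minute outputs.

The solver works in the gas-equivalent potential $\phi$ (continuous across
the interface; physical concentration is $\phi$ in gas and $\phi/10$ in
PDMS), discretised by finite volumes with harmonic-mean face conductances,
so the partition jump and flux continuity hold exactly at the interface and
a closed-box variant conserves partition-weighted mass to solver precision.
Time integration is backward Euler on the *combined*
advection–diffusion operator — implicit first-order upwind advection
assembled into one sparse matrix, LU-factorised once and reused for all
steps (default 1-s steps on a 2000 × 120 grid; about a minute on one CPU).
Treating the two terms in a single solve matters: the channel residence time
(≈ 0.14 s) is so far below the diffusion timescales that any splitting of
advection from diffusion leaves one step's worth of PDMS influx in the
channel snapshot — a dt-dependent artifact roughly ten times the true
advective balance at 1-s steps. The implicit one-matrix form keeps the
quasi-steady balance $u\,\partial_x C = $ influx$/h$ exact at any step size,
is unconditionally stable, and is an M-matrix, so the discrete maximum
principle holds.

Two boundary-condition readings deserve note. First, the 10:1 partition is
read as $C_\text{gas} : C_\text{PDMS} = 10 : 1$ at equilibrium; the opposite
reading is exposed as `partition_gas_rich = FALSE`. With percent units kept
per phase, a uniform 21% initial state is *not* an interfacial equilibrium
under either reading — the PDMS reservoir (equivalent to 210% gas-phase
potential) feeds the channel throughout the transient, which is precisely
the load the perfusion must clear. Second, the lateral ($x = 0, L$) PDMS
faces default to no-flux symmetry planes: the unrolled serpentine has no
physical lateral ambient surface (the folds continue inside the slab), and
clamping those faces to ambient creates a boundary-condition singularity at
the channel exit corner whose local maximum grows under grid refinement
instead of converging; `lateral_ambient = TRUE` restores the literal
clamped reading. Away from that corner the 60-s channel maximum changes by
well under 1% per grid halving at the resolutions used here (the convergence
test uses 250×58 vs 500×116 cells).

Embryo oxygen consumption, the liquid (PBST) phase, the 3D serpentine
geometry and the loading hydrodynamics are out of scope.

## Problem sizes and reproducibility

Every stochastic quantity derives from a single integer seed (cohort seeds
are drawn once from the master seed; the generator saves and restores the
session RNG). The shipped analyses use the study-scale sizes: 35 control and
14 treated embryos of 180 one-minute frames, the full 2000 × 120 transport
grid for the headline oxygen bounds, and coarser grids (50–500 cells per
side) for the conservation, equilibrium and convergence checks, where the
properties under test are resolution-independent. Rendering and segmenting
full image stacks is the one expensive path (≈ 0.7 s per 480² frame), so
image-based checks run on representative frames; the trace-based pipeline —
which is what the biology rests on — is always exercised end to end.

## Known limitations

Minutes-scale quantisation dominates the error budget of every timing
estimate (the ±1-frame tolerances in the tests are exactly that); the
arrest-interval length carries two quantised edges and can deviate by up to
about 1.5 frames in unlucky noise draws. The stage-5 end convention is a
package definition — the furrow is a morphological event that a fluorescence
trace can only proxy. The first-order upwind advection adds numerical axial
diffusion $\sim u\,\Delta x/2$; at the default 20-µm cells this smooths the
along-channel profile by a few percent of its value, conservatively
*raising* the reported channel maxima. And the t-test layer reproduces the
reporting convention it mirrors (raw per-metric p-values); it is not a
recommendation against multiplicity correction in new analyses.
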