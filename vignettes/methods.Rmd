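---
title: "Peri-ripple analysis of CA1-RSC interactions: models and methods"
author: "swrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-ripple analysis of CA1-RSC interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

swrpipe analyses simultaneous hippocampal CA1 and retrosplenial cortex
(RSC) recordings around sharp-wave ripples (SWRs): sleep scoring, event
detection, peri-event spike statistics, assembly reactivation, directional
GLM prediction, cell typing, cross-session unit tracking, and spatial
coding on a figure-eight maze.  This vignette explains the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
standard recipes leave the design open.

## Session model

All data live on a single session clock in seconds.  Intervals are
half-open `[start, end)` so abutting intervals concatenate without overlap;
sample `i` (0-based) of a signal occurs at `t0_s + i / rate_hz`.  A
`session` binds sampled signals (CA1 LFP, RSC LFP, EMG at 1250 Hz), sorted
spike trains with region labels, typed event interval sets, a hypnogram,
and (for task sessions) a trajectory and trial table.  On disk a session is
a directory of raw little-endian float32 signals with JSON sidecars plus
TSV tables; spike times are printed at 17 significant digits so a write /
read round trip is bit-exact.

## Sleep scoring

Wake is flagged wherever the z-scored EMG envelope (20-150 Hz band-pass,
rectified, 50-ms Gaussian smoothing) exceeds a threshold (default 0.5 SD;
the threshold is a configuration value because only its existence, not its
value, is standard).  Among immobile periods, the theta/delta ratio
(6-10 Hz over 1-4 Hz power) splits REM (>= 2) from NREM (< 2).  Stages
shorter than 30 s and 5-s windows straddling stage changes are relabelled
"other" (transition).

Two numerical choices deserve attention.  First, the canonical
"256-sample" ratio window cannot be taken at 1250 Hz: a 0.2-s window has a
raw frequency resolution of ~4.9 Hz and contains no 1-4 Hz information at
all.  `theta_delta_ratio()` therefore decimates the LFP to 125 Hz (9th of
the default rate, anti-alias filtered), making the 256-sample window 2.05 s
-- the shortest window that resolves the delta band.  Band power comes from
a Hann-tapered, zero-padded periodogram per window, so theta sidelobes do
not leak into the delta band.  Second, the ratio trace is smoothed with a
5-s Gaussian on the window grid: a 50-ms kernel -- natural for the EMG
envelope -- is inert on a 2-s grid, and without stage-scale smoothing the
ratio's sampling noise fragments NREM into spurious sub-30-s REM runs that
the transition rule then deletes.  Both settings are arguments.

## Event detection

Every envelope detector shares one normalisation: band-pass (zero-phase
3rd-order Butterworth), square, smooth with a short Gaussian, z-score over
the signal.  Thresholds are in SD units of that trace.

* **Ripples** (CA1, 140-250 Hz): events where the normalised power stays
  above 1 SD for 15-200 ms and peaks above 4 SD; events separated by less
  than 20 ms are merged before the duration test (merging first maximises
  agreement with the standard toolbox ordering).  The envelope smoothing SD
  is 12.5 ms: long enough that the squared 180-Hz carrier does not dip
  through the sustain threshold twice per cycle, short enough that a 40-ms
  burst is not washed out.
* **Sharp waves** (CA1, 5-40 Hz, z-scored): excursions beyond 2.5 SD
  lasting 20-400 ms.  A band-limited deflection is necessarily multiphasic,
  so thresholding the absolute value splits every real event into a main
  lobe plus side-lobe detections; the detector therefore thresholds a
  single polarity (negative by default, the stratum-radiatum convention),
  configurable via `polarity`.
* **SWRs**: ripples that overlap a sharp wave and whose peak lies inside
  the valid states (NREM in sleep; immobility below 3 cm/s in task
  sessions).  Peak amplitude stratifies SWRs into small (> 4 SD), medium
  (> 6 SD) and large (> 10 SD) classes.
* **Delta waves** (RSC, low-passed below 4 Hz, z-scored D(t)): candidates
  are positive lobes between zero crossings, ending at the following
  trough; a candidate is kept when the onset-to-trough duration is
  150-450 ms and either D(peak) > 2 with D(end) <= 0, or D(peak) > 1 with
  D(end) < -1.5.
* **Spindles** (RSC, 10-20 Hz): normalised power above 2.5 SD for more
  than 500 ms, peaking above 5 SD; events closer than 400 ms are combined
  and merged events longer than 3 s are discarded.
* **OFF periods**: maximal intervals with zero spikes pooled over at least
  5 RSC units, longer than 100 ms; OFF periods separated by less than 5 ms
  merge.  Because the rule operates on exact spike times the implementation
  is integer-exact and is verified against a literal merge-sort oracle.

## The synthetic-data generator

The generator is first-class, tested code: it produces sessions whose
every spike and LFP event is attributable to a recorded ground-truth
cause, under one seeded RNG stream.

**LFP.** The background is 1/f noise (alpha = 1).  Three deliberate
departures from plain Gaussian noise make the detector benchmarks
meaningful:

1. *Stabilised band envelopes.*  The amplitude envelope of the >100 Hz
   background (and of the 0.3-4 Hz RSC background) is flattened by its
   running RMS.  With within-session z-normalisation, a Gaussian-envelope
   background in the ripple band crosses a 4-SD peak threshold hundreds of
   times per 10 minutes -- chance envelope bursts would dominate any
   precision measurement.  Real NREM ripple-band background sits far below
   ripple amplitude; light-tailed envelopes encode that regime explicitly.
2. *In-band suppression during events.*  Inside each inserted event's
   window, the background's component in that event's detection band is
   suppressed, so the inserted waveform *is* the local band content.
   Without this, band cross-terms between event and background spread the
   achieved normalised amplitude by several SD around its target.
3. *Amplitude calibration in detector units.*  Event amplitudes are
   requested in detector SD units.  Calibration measures each event's
   isolated contribution to the detector trace against the composite
   trace's scale and iterates to the target, so ground truth records both
   the design amplitude and the achieved one.

Defaults: 60 ripples (180 Hz, 40-100 ms, 6 SD = 1.5x the peak threshold)
riding on sharp waves (60-150 ms, 4.5 SD), 80 delta waves (down-up-down,
~230-400 ms, 5.5 SD), 30 spindles (13 Hz, waxing-waning, 0.85-0.95 s,
6 SD) per 10 NREM minutes.  The spindle amplitude deserves a note: for 30
spindles sustaining 2.5 SD for over 500 ms in 600 s, the events' own
contribution to the band's variance bounds the attainable z-scored peak
below about 7 -- normalised amplitude is a budget, not a dial.  6 SD
leaves ~20% slack while exceeding every detection threshold.  NREM CA1
additionally carries continuous 0.5-3 Hz activity (large irregular slow
activity) so that the theta/delta ratio behaves as it does in real NREM;
REM carries 7.5-Hz theta; wake carries modest theta plus high-variance,
bursty EMG.

**Spikes.**  Trains are inhomogeneous Poisson by thinning with
rate = baseline x state factor x peri-SWR kernel x coupling x assembly.
Kernels are multiplicative Gaussian bumps in lag (defaults: CA1 +30 ms,
gain 3; RSC -50 ms, gain 2 -- shapes only; magnitudes are free
parameters).  A per-SWR latent excitability e_k ~ Gamma(2, 2) (mean 1)
scales the source region's bump with exponent 1 and the target's with the
configured coupling strength, which is the simplest mechanism that makes
directional GLM prediction succeed from the source's bump window and fail
from earlier windows.  A cross-region assembly (first m cells of each
region) co-fluctuates per 100-ms bin during running (shared log-normal
gain) and is re-expressed at SWRs with configurable strength.

**Task sessions.**  The figure-eight maze is 78 x 52 cm with a 30-cm
usable stem split into three 10 x 6 cm subareas.  Trials alternate L/R
with a configurable error rate (incorrect trials are excluded from stem
analyses); per-trial mean speed jitter (+-5 cm/s) and variable inter-trial
pauses (1-6 s) keep the behaviour aperiodic -- with strictly periodic
trials, a 10-30-s circular shift re-aligns a speed cell's rate with the
speed rhythm and the shuffle null loses its meaning.  Units carry place
fields (Gaussian, 8 cm), subarea profiles, trial-type gains in a stem
subarea (splitters), or linear speed tuning (rate = 0.2 x speed).

**What the generator does not emulate.**  No biophysics, no waveform
drift physics, no theta phase coding, no replay sequence content, no
electrode artifacts, and real background envelopes are heavier-tailed than
the stabilised ones.  Passing benchmarks therefore demonstrates that the
implementations follow their rules and have calibrated error rates under
clean conditions -- not that the detectors' absolute error rates transfer
to any particular recording.

## Peri-SWR spike statistics

PSTHs use 1-ms bins over +-1 s around eligible SWRs (greedy earliest-first
selection with >= 300 ms separation and the full window inside the epoch;
at least 50 events or the session is skipped).  Each unit's rate histogram
is z-scored against its own -1 to -0.5 s baseline and smoothed with a
20-ms-SD Gaussian.  Internally the lag histogram is built once from
(spike, anchor) lag pairs augmented with epoch-wrapped spike copies, which
makes shuffles exact and cheap.

The modulation test scores the summed squared difference between the PSTH
and the mean of shuffled PSTHs inside +-200 ms (RSC) or 0-100 ms (CA1),
comparing the real score with each shuffle's.  The displacement "by a
random amount up to +-0.5 s" admits three readings, all provided; the
default (`mode = "event"`) shifts each event's peri-SWR spike pattern by
its own uniform amount -- equivalently, jitters each anchor -- and then
re-imposes the anchors' minimum-separation rule on the surrogate windows,
so the null matches the data's window structure in count and spacing.
The whole-train variant (`mode = "shift"`) is structurally flawed for
this score: a shifted train carries an intact copy of the response, and
whenever the shift leaves that copy inside the scoring window (roughly a
third of the time for a +-200-ms window against +-0.5-s shifts) the
shuffle's score matches the real one, bounding the attainable p near
0.15 regardless of effect size.  Per-spike jitter (`mode = "jitter"`)
has no floor but adds placement variance to every null PSTH and is
mildly conservative.  With the default event mode and the 20-ms-smoothed
score the empirical size on homogeneous Poisson units is 3.5-4% at
alpha = 0.05 (mildly conservative; scoring the raw histogram is almost
exactly sized but loses most of the power for broad rate bumps -- the
smoothing that concentrates a bump against noise also correlates
neighbouring bins and slightly inflates surrogate scores), and power for
2x rate bumps over ~60 events exceeds 90%.  The smoothed PSTH is scored
by default (`smooth = FALSE` disables).

## Reactivation

Pairwise CA1-RSC correlations use Pearson r on 50-ms counts per phase;
the task-run significance class (positive / negative / unreliable) comes
from circular-shift surrogates (100 draws, two-sided 5%).  The template is
`C = t(Z_CA1) %*% Z_RSC / n_bins` on z-scored 100-ms run-epoch counts --
the cell-pair correlation matrix (n_CA1 x n_RSC).  A direct reading of
the template product with bins-by-cells matrices on both sides would be
dimensionally inconsistent (a bins-by-bins matrix); the cell-pair form
is the standard explained-covariance construction and is what downstream
projection requires.  Sleep counts are z-scored with NREM statistics
(configurable), projected per bin as `R(t) = z_CA1 C z_RSC'`, and R is
z-scored over the epoch.  Peri-SWR reactivation averages R in +-1 s around
SWR onsets; the null redraws matched numbers of random onsets 100 times,
and a one-sided signed-rank test compares real lag-0 values against the
null mean.

One property matters for interpretation: the test detects *any*
SWR-locked cross-regional co-activation, not reactivation specifically.
Generic peri-SWR rate bumps shared by all cells project onto a
positive-sum template and genuinely elevate R at lag 0.  The calibration
null in the test suite therefore switches the peri-SWR kernels off as well
as the injected reactivation; with kernels on and injection off the test
still fires occasionally, and on real data a lag-0 effect should be read
as "SWR-locked co-activation consistent with the run template", with the
template-specificity control (cross-validated template on independent
data) as the sharper tool.

## GLM prediction

Per SWR, the predictor vector holds each source cell's spike count in a
100-ms window relative to onset and the outcome is the predicted cell's
count in its window (counts enter raw, with an intercept).  A 5-fold
cross-validated Poisson GLM (log link; Poisson is the canonical pairing
for a count outcome with a log link) yields the mean absolute prediction
error; the baseline error re-scores the fitted predictions against 100
permutations of the test fold's outcomes; gain = mean baseline error /
mean real error.  Degenerate folds fall back to a ridge-stabilised IRLS
refit; a zero real error gives gain 1 when the baseline error is also zero
and a configurable cap otherwise.  The control distribution re-runs the
identical machinery after whole-set predictor-to-SWR permutations (100 by
default), and significance compares real and control gains with a
two-sided rank-sum test across predicted cells.  SWR-occurrence prediction
works the same way with a stratified-fold binomial GLM on 100-ms bins.

## Cell typing and tracking

RSC units: average waveforms normalised by peak-to-trough amplitude, PCA
to 3 components, Ward-linkage hierarchical clustering cut at 3 clusters;
the extreme clusters by mean trough-to-peak duration become wide
(excitatory) and narrow (inhibitory), and the middle cluster joins its
nearer centroid carrying a review flag.  CA1 units follow the literal
rule: trough-to-peak <= 0.425 ms is a narrow interneuron; > 0.425 ms with
ACG tau_rise <= 6 ms is pyramidal; everything else is unclassified.  The
ACG rise constant comes from a 0.5-ms-bin, +-50-ms autocorrelogram fitted
with the standard rise-decay-plus-burst form; because the decay and burst
components trade off against the rise near the origin, a rise-only model
is fitted first and seeds the full fit, which is kept only when it
clearly improves the residual.

Tracking compares each pre-phase unit with the post-phase units on its
channel.  Waveforms are conditioned first (Gaussian smoothing, SD 2
samples, plus 3x spline upsampling): average-waveform noise otherwise
jitters the discrete peak positions that the local similarities
`max(0, 1 - |pre - post| / pre)` (trough-to-peak duration, trough-to-peak
amplitude, peak-to-trough amplitude) depend on.  Global similarities come
from DTW-aligned normalised waveforms: 1 minus the maximum pointwise
difference, the Pearson correlation of the warped waveforms, and the
length ratio penalising warping.  The DTW band is 5% of the waveform
length (~0.05 ms): wide enough to absorb sampling offsets, narrow enough
that one cell type cannot be warped onto another -- with an unconstrained
band, wrong-pair warped correlations reach 0.999 and the score stops
discriminating.  The final score is `(1/5) ||local||_2 + (4/5)
||global||_2` (norms unnormalised by component count); acceptance requires
the best score plus warped correlation >= 0.95 and duration similarity >=
0.7, one-to-one on the post side, with review flags replacing manual
curation when the runner-up is within 0.05 or a post unit was contested.
Three-phase tracking intersects pre/post and task/post matches on the post
unit.

## Spatial coding

Rate maps use 0.36-cm square bins (configurable -- at this
resolution a field spans hundreds of bins, which interacts with the field
rule below), a 3-cm/s speed filter, 5 x 5-bin Gaussian smoothing of spike
and occupancy maps before division, and a 200-spike inclusion threshold.
The conventional field rule -- at least 40 supra-threshold bins within a
7 x 7-bin area, each above twice the mean rate -- is internally tense (a
7 x 7 box holds at most 49 bins); it is implemented as a connected
supra-threshold component of >= 40 bins whose bounding box fits in 7 x 7,
with every constant exposed.  Stem analysis computes per-correct-trial firing rates in the
three subareas and runs the two-way ANOVA (subarea x trial type) at
alpha = 0.05: a trial-type main effect or interaction makes a splitter; a
subarea-only effect makes a location-related cell.  Defining the speed
score as a correlation between the speed tuning curve and speed itself
would be circular; following the speed-cell literature it is implemented
as the absolute Pearson
correlation between the instantaneous rate (per-frame counts smoothed over
250 ms) and instantaneous speed over 5-35 cm/s, with the binned tuning
curve reported descriptively.  A speed cell needs the score above the 99th
percentile of 100 circular trajectory shifts (uniform 10-30 s) and a
correlation p below 0.01, and speed cells are removed from the stem labels.

## Pipeline and audit sizes

`run_pipeline()` chains scoring, detection, peri-SWR statistics,
reactivation, GLM and spatial stages over pre-sleep / task / post-sleep
triplets, writes every stage's tables, and stamps the bundle with the
configuration hash and seed; identical inputs give byte-identical bundles.
The test suite validates each stage on generated sessions: 10-minute NREM
sessions for detectors (60/60/80/30 inserted events), 7-minute sessions
for scoring (20 seeds), 400 Poisson units at 200 shuffles for the
modulation test's size and 40 bump units for its power, 50 seeds each for
reactivation injection and null, 30 seeds per GLM window, 50 seeds for
tracking and typing, 40 task sessions for spatial classification, and 1000
random rasters for the OFF oracle.  These sizes are the package's audit
choices; the acceptance script (`scripts/acceptance.R`) recomputes the
same quantities at reduced replicate counts.

## Known limitations

Clock alignment across separately recorded phases is taken from explicit
per-file offsets and never guessed.  The sharp-wave criterion applies to
the channel-average CA1 LFP (configurable) rather than per channel.
Detector error rates on real recordings depend on band-envelope tails the
generator deliberately lightens.  The reactivation test's specificity
caveat above applies to real data as well.  Manual curation steps of the
original workflow (state editing, match vetting) are replaced by review
flags and QC outputs, not reproduced.
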