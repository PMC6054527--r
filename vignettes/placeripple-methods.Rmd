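---
title: "Methods: place coding, ripples and within-ripple coactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place coding, ripples and within-ripple coactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`placeripple` implements the analysis chain used for hippocampal CA1 tetrode
recordings on linear tracks with flanking rest sessions: place-cell rate
curves and spatial information, place-field geometry, theta phase
precession, sharp-wave-ripple detection, and the normalized within-ripple
pairwise coactivity statistic, together with group-level comparisons and a
synthetic-data generator that makes every stage testable against known
ground truth. This vignette records the models, the parameters that matter,
and the numerical decisions taken where the conventions of the field leave
room.

## Behavioral preprocessing

Positions (sampled at 33 Hz) are projected onto the 1-D track path; the two
running directions are always analyzed as separate trajectories, since CA1
place fields on tracks are typically directional. A lap is a continuous
excursion from one 10 cm end zone to the other; turn-arounds are discarded.
Running speed comes from a 0.25 s boxcar-smoothed position differentiated
centrally — the smoothing suppresses 33 Hz tracker jitter that would
otherwise dominate the finite difference. Samples are masked (excluded from
occupancy and spike assignment alike) when they fall in a stop — a maximal
run of speed strictly below 3 cm/s lasting strictly more than 1 s — or
within 4 cm of a reward site. The stop thresholds are the field's standard
ones; the reward radius is a package choice (two spatial bins, the minimal
exclusion consistent with dropping "the bins at the reward site") and is
configurable in `motion_filter_params()`.

## Rate curves, spatial information, fields

Each trajectory is divided into 2 cm bins. The rate in bin $i$ is
$x_i = c_i / t_i$ (spikes over occupancy seconds, pooled across laps), and
the curve is smoothed with a Gaussian kernel of $\sigma$ = 2 bins, truncated
at $\pm 4\sigma$ and renormalized at the curve ends — no wraparound on a
linear trajectory, and no zero-padding bias. Bins never occupied carry no
rate and are excluded from the occupancy distribution $p_i$ rather than
interpolated. Spatial information is the Skaggs per-spike measure

$$\mathrm{SI} = \sum_i p_i \frac{x_i}{\lambda}\log_2\frac{x_i}{\lambda},
\qquad \lambda = \sum_i p_i x_i,$$

computed on the smoothed curve by default (smoothing precedes the
information step in the standard processing order; the raw-curve variant is
available via `use_smoothed = FALSE`). A silent cell has undefined SI and is
reported missing, never zero. Stability is the Pearson correlation of the
two sessions' curves over bins occupied in both; fewer than three common
bins, or a flat curve, gives a missing value.

Place fields are local peaks of the smoothed curve with rate at least 1 Hz;
boundaries extend to the last bin at or above 10% of that field's peak, and
fields separated by at most 6 cm are merged iteratively until a fixed point
(so chains of near peaks collapse), the merged peak being the maximum over
members. Ties between equal-rate bins break toward the leftmost bin for
determinism. Units are classified as putative pyramidal when the
session-wide mean rate is at most 7 Hz, and as run-active when, being
pyramidal, their within-lap mean rate exceeds 0.5 Hz on at least one
trajectory of at least one running session; both inequalities are applied
exactly as stated (7.0 Hz is pyramidal; 0.5 Hz is not run-active).

## Theta phase precession

Spike phases are taken from the analytic signal of the theta-filtered
(6-10 Hz) LFP, interpolated at spike times after unwrapping, with the
oscillation trough at 0 degrees (a convention choice; the fits are invariant
to it). The theta band at a 2 kHz sampling rate sits at normalized
frequencies of 0.006-0.010, where a high-order IIR band-pass is numerically
fragile, so the theta filter is an exact zero-phase FFT band-pass; the
ripple band (100-250 Hz) uses a conventional 4th-order Butterworth applied
forward and backward.

Within a field, positions are converted to distance traveled into the field
along the running direction, so slopes from the two trajectories are
comparable. Two fits are computed on the pooled spikes (at least 5
required):

* **Optimal linear regression.** Phases are rotated by every integer shift
  $\delta \in \{0,\dots,359\}$ degrees, wrapped into
  $[\delta, \delta+360)$, and an ordinary least-squares line of phase on
  position is fitted; the rotation maximizing $|r|$ wins, with ties going to
  the smallest shift. This makes the fit invariant to global phase rotation
  but limits it to precession spanning less than one cycle.
* **Circular-linear regression.** The slope $a$ (cycles/cm) maximizes the
  mean resultant length
  $R(a) = \bigl|n^{-1}\sum_j e^{i(\phi_j - 2\pi a s_j)}\bigr|$ over a
  bounded range ($\pm 0.05$ cycles/cm by default — at least two cycles
  across a 40 cm field). $R(a)$ is multimodal with ripples on the scale of
  $1/\mathrm{range}(s)$, so the maximization uses a dense grid (step
  $10^{-3}$ cycles/cm) followed by local refinement; the offset is the
  argument of the resultant at the optimum. The circular-linear correlation
  between the phases and the fitted circular variable
  $\theta_j = 2\pi|a|s_j$ uses the sine-product formula with circular
  means, signed by the slope direction; identical phases leave it
  undefined (missing).

## Ripple detection

The rest-session LFP is ripple-band filtered and the standard deviation
$\sigma$ of the filtered trace computed over the *entire* session, events
included — the literal reading of the thresholding convention, and the one
that keeps the procedure free of circular exclusion rules. Candidate events
are excursions of the analytic-signal envelope above $2.5\sigma$ containing
at least one sample at or above $6\sigma$; neighbors closer than 30 ms are
merged, and events are kept if 30-500 ms long (merging precedes the
duration filter). The envelope is used rather than the rectified trace
because it is phase-invariant; a gain change of the recording leaves the
detected set identical, since all thresholds are $\sigma$-relative.

Per event, amplitude is the absolute value of the most negative trough of
the filtered trace (reported in input units), and frequency is estimated
from the trough count as $(n_{\mathrm{troughs}}-1)$ divided by the time
between the first and last trough. The naive "troughs over duration" form
is biased low by roughly one cycle per event duration (about 17 Hz for a
60 ms event) because the boundary half-cycles are miscounted; the
within-trough-span form is unbiased for a stationary oscillation. A
spectral-peak alternative (`freq_method = "spectral"`) is provided; neither
is claimed to be canonical, as the field uses both.

## Within-ripple coactivity

Each ripple event is padded by 150 ms on both sides; overlapping padded
windows are merged and their total duration is $T$. For a cell pair, spike
time differences $t_b - t_a$ are histogrammed in 20 ms bins spanning
$\pm 230$ ms (centers $-220 \dots 220$ ms, covering the baseline lag
windows exactly), smoothed by 5-bin nearest-neighbor averaging with a
shrinking window at the edges (zero-padding there would bias precisely the
baseline lags), baseline-subtracted using the mean smoothed value at lags in
$[-220,-180] \cup [180,220]$ ms, and rescaled by
$\sqrt{n_a n_b \Delta / T}$ — the square root of the per-bin coincidence
count expected from two independent Poisson trains with the same in-window
spike counts ($\Delta$ = bin width). This is the unique dimensionally
consistent per-bin expectation; an alternative normalizing by the
expectation summed over all lag bins is available (`norm = "total"`).
Coactivity is the mean normalized value over lag bins within
$\pm 50$ ms.

One numerical decision deserves emphasis: the correlogram is computed on
**window-concatenated time** (inter-window gaps removed) rather than by
pairing spikes only within the same window. With same-window-only pairing,
the number of spike pairs available at lag $\tau$ is proportional to
$\sum_w (T_w - |\tau|)$, so the expected correlogram is triangular in lag
even for independent trains, the $\pm 200$ ms baseline sits systematically
below the 0-lag expectation, and "coactivity" is substantially positive
under the null. Concatenation makes the retained point process stationary
under a Poisson null, so the per-bin expectation $n_a n_b \Delta/T$ holds at
every lag and independent pairs are centred at zero — the property the
normalization is meant to deliver, and the one the test suite verifies.
The residual edge effect (lags truncated at the ends of the concatenated
record) is of order $\tau_{\max}/T$ and removed by the baseline
subtraction.

Pairs are unordered, with the lag sign fixed by sorted cell id; a pair with
a silent member yields a missing value. For pre/post comparisons only pairs
recorded in all required sessions are used.

## Group statistics

Summaries are medians with interpolated quartiles (`quantile` type 7).
Comparisons use the two-sided Wilcoxon rank-sum test, the paired Student's
t-test, and two-way ANOVA with interaction (genotype x session); all are
delegated to the corresponding base-R routines, with degenerate inputs
(all-tied samples, zero-variance differences, empty design cells) mapped to
the documented conventions rather than errors. The downsampling analysis
equalizes group sizes to the reference group's n (31 in the motivating
design): each of 200 iterations draws that many values *without
replacement* from every non-reference group — choosing a subset of cells,
not bootstrapping — runs the rank-sum test per requested comparison, and
the fraction of iterations with p < 0.05 is reported along with the full
p-value distribution. The reference group is never resampled. With the
seed fixed the whole procedure is bit-reproducible.

## The synthetic-data generator

The generator's role is to emulate the statistical structure the analyses
consume, with exact ground truth; its defaults are the study conditions the
package is tested under.

* **Track sessions.** A triangle-wave trajectory at 20 cm/s on a 200 cm
  track (typical mouse running), 33 Hz position samples, 20 laps per
  direction by default. Cells are Gaussian-tuned (sd 10 cm, peak 15 Hz)
  inhomogeneous Poisson processes simulated by thinning. The track LFP is a
  pure 8 Hz theta oscillation. Precession is imposed by moving each
  in-field spike within its theta cycle to the time whose phase equals
  `entry_phase + slope x distance_into_field + vonMises(kappa)` (slope
  -6 deg/cm by default — one cycle across the 6-sd field extent, the most
  a shift-based linear fit can represent; kappa = 4, about 30 degrees of
  jitter). The time displacement is at most half a theta cycle (about
  1.3 cm at the default speed), so spatial tuning is essentially
  unperturbed and the Poisson spike count is untouched.
* **Rest sessions.** The LFP is 1/f background noise scaled so its
  ripple-band sd defines the amplitude unit, which makes the 6-sd detection
  threshold meaningful and portable; ripples are Hann-windowed sinusoid
  bursts (150 Hz, mean 100 ms, peak 8 units) at exponential-gap times with
  a 200 ms minimum separation. Spike trains are homogeneous Poisson
  backgrounds (1 Hz). Pairwise synchrony is injected directly at the scale
  the coactivity statistic measures: per ripple and designated pair, with
  the configured probability, one spike is added to each cell inside a
  common 20 ms sub-window. Background trains are *not* ripple-modulated by
  default: common rate modulation inside windows shifts coactivity away
  from zero even for independent cells, and a clean null is what makes the
  injection dose interpretable.
* **Cohorts.** An animal contributes Pre-run rest, Run 1 track and Post-run
  rest sessions with 3 place cells (so a 7-animal control-like and
  9-animal mutant-like cohort carry 21 and 27 simultaneously recorded
  run-active pairs — the scale of the motivating dataset; with many more
  pairs per animal the pair-level paired t-test becomes anticonservative,
  because pairs within an animal share session-level variance). The
  control-like preset injects coincidence probability 0.01 in Pre-run and
  0.12 in Post-run (experience-driven synchrony increase); the mutant-like
  preset injects 0.12 in both (baseline hypersynchrony at the control
  post-run level, no increase). One global seed spawns per-session child
  seeds so sessions are independent but the whole cohort is reproducible.

What the generator does **not** emulate — and what passing tests therefore
do not certify on real data: sorting errors and unit drift, interneurons,
velocity-modulated theta and rate, sharp-wave polarity and multi-channel
structure, behavioral variability (variable speed, mid-track stops),
ripple-modulated background firing, and higher-order (beyond pairwise)
synchrony. Results on real recordings additionally depend on spike-sorting
quality, which is out of scope here.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale: one
10-minute rest session (and 100 white-noise sessions) for detector
calibration, 500 Poisson pairs for the coactivity null, five injection
levels x two sessions for the dose response, 50 seeded single-field cells
for field and precession recovery, the 7 + 9-animal cohorts for the
pre/post pattern, and 200-iteration downsampling. All randomness flows
from explicit integer seeds; identical seeds give bit-identical arrays,
tables and p-values.

## Known limitations

* The optimal linear regression cannot represent precession spanning more
  than one cycle; such fields are better served by the circular-linear fit.
* The per-event frequency definition is not standardized in the field; two
  estimators are offered and labeled.
* SI on smoothed curves is mildly biased toward lower values for very
  narrow fields (smoothing widens them); the raw-curve option quantifies
  the effect.
* The pair-level paired t-test treats pairs as independent; with many
  simultaneously recorded pairs per animal this is anticonservative, which
  is why cohort-level conclusions should be checked per animal as well.
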