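---
title: "Models and methods behind thetamaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thetamaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetamaze)
```

## The analysis problem

During place learning in a Morris water maze, the theta rhythm (4--12 Hz)
recorded in the supramammillary nucleus (SUM), medial septum (MS), dentate
gyrus (DG) and hippocampal field CA1 reorganises: in intact animals the
dominant frequency drifts upward across training days (roughly from 7
toward 8 Hz), relative power shifts from the 6.5--7 Hz bins into the
7.5--8.5 Hz bins, and the MS becomes more coherent with the hippocampus;
animals whose SUM serotonergic input has been lesioned show essentially
flat profiles and poor learning.  `thetamaze` implements the complete
analysis chain for such experiments -- spectra, coherences, peak tracking,
swim-trajectory metrics and the repeated-measures statistical battery --
together with a synthetic-cohort generator that reproduces both group
profiles with known ground truth, so every stage can be validated without
access to animal data.

## Spectral estimation

EEG is sampled at 1024 Hz and band-passed 1--100 Hz.  The band-pass is a
zero-phase frequency-domain filter with raised-cosine transitions (full
width 1 Hz around the low edge, 10 Hz around the high edge).  Two design
constraints drove this choice over a conventional IIR filter pair: the
response must be *exactly* flat across the analysis band (any ripple
biases relative power), and a constant input must map to zero output
without start-up transients, which forward--backward IIR filtering does
not guarantee.  The input is reflect-extended to an FFT-friendly length
and mirrored, so the periodic extension seen by the FFT is continuous;
boundary ringing is confined to roughly half a second at each end of a
record.

Records are cut into non-overlapping 2-s epochs from $t = 0$ (a trailing
partial window is discarded), giving a frequency resolution of exactly
0.5 Hz.  Per epoch, a rectangular-taper periodogram is evaluated and the
17 bins at 4.0, 4.5, ..., 12.0 Hz are retained; absolute power (AP) is
the mean over kept epochs, scaled so a unit-amplitude on-grid sinusoid
contributes its mean square (0.5) in a single bin.  Absolute units are
arbitrary throughout -- only relative power and natural-log AP are
compared.  A Hann taper (with coherent-gain correction) is available but
not the default: plain FFT of 2-s samples is the most literal reading of
the acquisition convention.  Relative power (RP) is each bin as a
percentage of the 4--12 Hz total (inclusive of both edge bins), so RP
sums to 100 by construction and is exactly invariant to amplitude
scaling.

Artifact screening replaces manual inspection with a reproducible rule:
an epoch is dropped when its peak absolute amplitude on any channel
exceeds 6 robust standard deviations (median absolute deviation x 1.4826)
of the whole recording.  The robust scale is estimated from at most
~16,000 evenly spaced samples, which is far past the point where the
estimate has stabilised.  Rejections are logged with reasons, and
rejecting *all* epochs is an error, never a silent empty result.

The theta peak frequency is the argmax of RP over the 5--10 Hz band (the
band used by all day-by-frequency comparisons), ties resolving to the
lowest frequency; a day's value is the mean of the four trial peaks.

## Coherence

Magnitude-squared coherence (MSC) uses the same kept 2-s epochs in a
Welch-style estimator,
$\gamma^2(f) = |\langle X Y^* \rangle|^2 / (\langle|X|^2\rangle \langle|Y|^2\rangle)$,
restricted to the 17-bin grid, for all six unordered pairs of the four
sites (pairs are stored alphabetically, so (MS, CA1) and (CA1, MS) are
the same pair).  At least two epochs are required, because the
single-segment estimate is identically 1; trials contributing fewer than
two epochs are excluded from coherence with a logged reason.  Daily
coherence is the epoch-count-weighted mean over the four trials
(an unweighted mean is available), since trials of unequal duration
contribute unequal numbers of epochs.  The estimator's small-sample bias
-- mean MSC near $1/K$ for $K$ independent segments -- is characterised by
a test rather than corrected, which documents why short trials would
inflate coherence if the minimum-epoch rule were relaxed.  The frequency
of the coherence peak (FCP) and its magnitude are extracted over the same
5--10 Hz band with the same tie rule.

## The synthetic cohort

The generator's defaults are the study conditions: 7 control (CTR) and 6
experimental (EXP) subjects; 6 training days of one 60-s basal record
plus 4 search trials (up to 60 s of searching followed by 15 s on the
platform, EEG recorded throughout), and a 30-s platform-free probe on day
7; EEG at 1024 Hz; a 1.5-m-diameter pool with a 9-cm platform centred in
the north quadrant at half the pool radius.

**Oscillators.**  Narrowband theta is modelled as a second-order
resonance: the spectral shape of a damped AR(2) process with pole radius
$e^{-\pi\,\mathrm{bw}/f_s}$, giving a controllable half-power bandwidth
(default 0.5 Hz).  The standalone oscillator
(`make_theta_oscillator()`) runs the AR(2) recursion directly; inside the
trial generator the same spectra are synthesised in the frequency domain
(random spectral lines with the AR(2) profile), which is statistically
equivalent for a stationary Gaussian process, makes each component's
expected power in any analysis bin an explicit band sum, and costs one
FFT per pair of components.  Components are rescaled to their exact
target variances after synthesis.

**Spectral learning profile.**  Rather than a single gliding frequency,
each group's theta is a mixture of a *low* (7 Hz) and a *high* (8 Hz)
shared driver whose weights shift across days (CTR: high-driver weight
0.10 to 0.90 over days 1--6; EXP: 0.10 throughout).  This reproduces the
empirical signature -- RP falling in the 6.5--7 Hz bins while rising at
7.5--8.5 Hz, with the daily dominant peak moving from 7.0 to 8.0 Hz --
and keeps the day-1 and day-6 peaks on-grid.  A `peak_schedule` option
substitutes a single driver per day when a simple peak is wanted.

**Coherence targets.**  Channels share the driver mixture and add
independent noise of *the same spectral shape* plus a $1/f$ background
(exponent 1, with a white floor; per-channel background band power is
`1/snr` of the shared-theta variance, default `snr = 3` during search).
Writing $g_i = S/(S + N_i)$ for channel $i$'s coherent fraction at the
driver bin, a pair's MSC there is $g_i g_j$ -- for the symmetric case
exactly the shared-source formula $(\mathrm{SNR}/(1+\mathrm{SNR}))^2$.
Per-pair targets are solved for channel gains by least squares in log
space; targets incompatible with a single shared driver (residual above
0.05), mixed zero/non-zero targets, or targets whose required independent
power is already exceeded by the background at the driver bin all raise
configuration errors naming the offending pair.  Default targets rise
from 0.25 to 0.60 across days in CTR (the range of the empirical MS-hippocampus
values) and stay at 0.25 in EXP.  Because one shared driver serves all
four channels, arbitrary *combinations* of pairwise targets are only
approximately realisable -- a documented limitation of the driver model.

**Swim model.**  Trajectories are correlated random walks at constant
speed (0.25 m/s -- the study reports velocities unchanged across days but
prints no number; 0.25 m/s is typical of adult rats) with time step
0.1 s and turning noise 1.5 rad/sqrt(s).  Each step the heading is pulled
toward the platform bearing by the fraction
$\min(1, \mathrm{gain} \cdot \Delta t)$ of the angular error (noise first,
pull second, so the infinite-gain limit is an exactly straight approach).
Wall contacts bounce the heading inward.  Goal-directedness rises across
days in CTR (gain 0.2 to 1.5, producing mean latencies falling from
~35 s to ~5 s) and stays at 0.2 in EXP (latencies ~30-45 s with frequent
timeouts), matching published control learning curves.  Start positions
sit on the wall at quadrant bisectors, facing inward, one quadrant per
trial in a per-day order shared by all subjects and permuted across days.
Probe trials remove the platform, keep the day-6 gain aimed at the
remembered location, and last exactly 30 s.

**Determinism.**  Every record's random stream is seeded by a hash of the
master seed and the (subject, day, trial, stream) indices, so a fixed
seed yields bit-identical cohorts regardless of which records are
materialised, and the streaming analysis path (`run_all()`) sees exactly
the data `simulate_cohort()` would store.

## Behavioural metrics

Escape latency is the time of the first sample inside the platform disc
(detection cannot precede one sample interval); timeouts record the 60-s
limit with a `guided` flag and are included in means.  Path length sums
segment lengths up to platform entry; mean velocity is path length over
latency by construction.  Quadrants are the 90-degree sectors bisected by
the compass directions, boundaries at 45, 135, 225 and 315 degrees, with
boundary points assigned counterclockwise; each segment is assigned to
the quadrant containing its midpoint, which makes per-quadrant distances
sum *exactly* to the path length, with discretisation error bounded by
the sampling density (halving a smooth path's sampling rate changes its
length by under 2%).

## Statistics

The battery wraps the standard R implementations behind explicit
contracts: Friedman's test (`Xr2`, mid-ranked ties) for daily latencies;
exact-distribution Wilcoxon and Mann-Whitney tests for small samples
(n <= 25, untied), normal approximation with tie correction otherwise,
with the method recorded; randomised-block ANOVA with Tukey HSD for
distances and velocities; paired t-tests with Bonferroni correction
(raw and adjusted p both reported, zero-variance differences flagged as
degenerate rather than yielding infinite t); and Pearson correlation of
daily peak frequencies between regions with the exact t-transform p.

The day x frequency repeated-measures ANOVA treats both factors as
within-subject (frequency at the eleven 0.5-Hz levels of 5--10 Hz, the
reconstruction consistent with the printed degrees-of-freedom patterns),
requires and validates a balanced design (replicates averaged first,
missing cells named), and reports conventional uncorrected F and df.
With an 11-level frequency factor sphericity is certainly violated, so
the pipeline also computes Greenhouse-Geisser corrected p-values
(`gg = TRUE`, the `run_all()` default) and uses those for inference;
the type-I simulations below justify this: with uncorrected df the flat
profile would reject too often, with the correction the empirical rate
is at or below nominal.  An optional day subset (e.g. days 1, 2, 5, 6,
the acquisition/consolidation contrast) reruns the same analysis on the
reduced design.

## What the tests do and do not show

The test suite validates every operation against analytic oracles (exact
bin placement of on-grid tones, brute-force DFT and sums-of-squares
computations, exact enumeration for small-sample nonparametrics) and the
generator against its own calibration: shared-source coherence targets
{0.25, 0.49, 0.81} recovered within 0.05 at 100 epochs, on-grid peaks
recovered in >= 95/100 seeds at SNR 2, CTR-profile cohorts (n = 7)
yielding a significant day x frequency interaction in >= 90% of 20
simulations while flat EXP-profile cohorts reject at no more than the
nominal rate, and CTR swim paths shortening from day 1 to day 6 in >=
90% of 20 seeds.  Simulation sizes in the routine suite (cohort counts,
seeds per Monte-Carlo) are chosen so the whole suite runs in minutes on
one core while keeping the binomial uncertainty of each rate well inside
its margin.

The generator emulates the *structure* of the data -- narrowband
oscillators over 1/f background, coherence through shared drivers,
goal-biased random-walk swimming -- not its biophysics.  It contains no
asymmetric electrode gains drifting over days, no movement artifacts
beyond what the amplitude rule is tested with, no within-trial
non-stationarity (the oscillator profile is fixed within a trial), no
volume conduction, and no behavioural strategies (thigmotaxis, chaining).
Passing tests therefore demonstrate that the pipeline measures correctly
whatever matches its model assumptions, not that those assumptions span
everything real recordings do.

## Numerical and design choices

* Frequencies are kept as decimals on the 0.5 grid everywhere (no float
  keys); bins 4.0 and 12.0 are both inside the normalisation band (17
  bins).
* Ties in peak and FCP extraction go to the lowest frequency,
  deterministically.
* MSC is clipped to [0, 1] only against floating-point overshoot of the
  Cauchy-Schwarz bound.
* Search records are analysed up to platform entry by default
  (`include_platform = TRUE` keeps the 15-s platform period); when the
  platform period is excluded anyway, `run_all()` also skips generating
  it (`trim_generation`), which changes no analysed number.
* Trials whose analysed segment is shorter than one epoch are excluded
  with a logged reason; shorter than two epochs, excluded from coherence
  only.
* The EDF import mentioned alongside the delimited-table format is not
  provided; the text format (17-significant-digit, lossless round-trip)
  is the interchange representation.

## Known limitations

* A single shared driver cannot hit arbitrary per-pair coherence
  patterns; requests outside its reach error out rather than silently
  approximating.
* The oscillator model is stationary Gaussian; empirical theta is
  asymmetric and amplitude-modulated by behaviour.
* The GG epsilon is estimated from the sample covariance, which is noisy
  for 7 subjects and 50-dimensional contrasts; the resulting inference is
  conservative (the type-I simulations bear this out).
* Quadrant assignment by segment midpoint, not boundary clipping: exact
  conservation is bought at a discretisation error that vanishes with
  sampling density.
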