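# thetamaze

Spectral, coherence and behavioural analysis of multi-site theta-band EEG
recorded while rats learn a Morris water-maze, with a synthetic-cohort
generator that makes the whole pipeline testable end to end.

## Who this is for

Electrophysiologists analysing local field potentials from the
supramammillary nucleus (SUM), medial septum (MS), dentate gyrus (DG) and
hippocampal CA1 during spatial learning — and anyone who needs a
reproducible, oracle-tested reference implementation of the standard
analysis chain for such experiments: theta-band power spectra,
inter-region coherence, peak-frequency tracking, water-maze performance
metrics, and the accompanying repeated-measures statistics.

## The quantities it computes

EEG (1024 Hz, band-passed 1–100 Hz, automatic amplitude artifact
rejection) is cut into 2-s epochs, giving exactly 0.5 Hz resolution.
On the 4–12 Hz grid (17 bins) the package computes, per trial and
region:

* **Absolute power** `AP(f)` — mean rectangular-taper periodogram over
  epochs — and its natural log `nl(AP)`;
* **Relative power** `RP(f) = 100 · AP(f) / Σ₄₋₁₂ AP` (percent of the
  theta band; sums to 100 by construction);
* **Peak frequency** — argmax of RP over 5–10 Hz, daily value = mean of
  the four trial peaks — and its Pearson correlation between regions
  across (subject, day) points;
* **Magnitude-squared coherence** for all six region pairs on the same
  epochs, `γ²(f) = |⟨XY*⟩|² / (⟨|X|²⟩⟨|Y|²⟩)`, with the frequency of the
  coherence peak (FCP) and its magnitude;
* **Swim metrics** from (t, x, y) trajectories: escape latency (60 s
  cap), path length, mean velocity, and per-quadrant distances in the
  probe trial (conserving total path length exactly);
* **Statistics**: day × frequency repeated-measures ANOVA (optionally
  Greenhouse–Geisser corrected), Friedman + Wilcoxon for latencies,
  Mann–Whitney between groups, randomised-block ANOVA + Tukey HSD for
  distances, paired t with Bonferroni.

A simulation module generates cohorts of both experimental profiles with
known ground truth: a control (CTR) group whose theta peak drifts from
7 to 8 Hz across six training days with rising MS–hippocampus coherence
and shortening swim paths, and a lesion-like (EXP) group that stays flat.
Coherence targets are hit analytically: channels share a narrowband
driver and the shared-source identity `γ² = (SNR/(1+SNR))²` fixes the
independent-noise budget per channel.

## Worked example

Simulate and analyse a full cohort (7 CTR + 6 EXP subjects, 6 training
days × 4 trials + probe) and look at the headline results:

```r
library(thetamaze)
cfg <- sim_config(seed = 7)
rep <- run_all(cfg, days_subset = c(1, 2, 5, 6))
print(rep)
#> <theta_report> 403 records analysed (25 exclusions logged)
#>   spectra: 25704 rows (13 subjects x 7 days)
#>   coherence: 38556 rows, 6 pairs
#>   mean latency CTR: d1 33.1s, d2 19.9s, d3 11.7s, d4 8.7s, d5 6.4s, d6 5.4s
#>   mean latency EXP: d1 37.7s, d2 28.0s, d3 40.2s, d4 26.9s, d5 30.3s, d6 45.2s
```

The CTR group learns (latencies fall from 33 to 5 s) while EXP does not.
The spectral signature follows: the daily CA1 peak frequency climbs from
7.0 to 8.0 Hz in CTR and stays at 7.0 Hz in EXP,

```r
aggregate(peak_freq ~ group + day,
          rep$daily_peaks[rep$daily_peaks$region == "CA1", ], mean)
#>      day
#> group    1    2    3    4    5    6
#>   CTR 7.02 7.12 7.49 7.45 7.90 7.96
#>   EXP 7.00 6.98 7.00 7.04 6.98 6.96
```

and the day × frequency interaction separates the groups cleanly
(Greenhouse–Geisser corrected p):

```r
rep$stats$rp_rm_anova_CTR_CA1   # day:freq F(50, 300) = 16.8, p_gg = 9.5e-06
rep$stats$rp_rm_anova_EXP_CA1   # day:freq F(50, 250) =  1.2, p_gg = 0.35
```

Daily peak frequencies are correlated across regions in CTR
(CA1–SUM: r = 0.81, p = 1.2e-10), and day-6 MS–CA1 coherence at 8 Hz
reaches 0.72 in CTR versus 0.25 in EXP.  Friedman tests on daily
latencies give Xr² = 28.2 (p = 3.3e-05) for CTR and Xr² = 9.7
(p = 0.084) for EXP.

Tidy tables for every figure-level quantity (`spectra`, `daily_peaks`,
`coherence`, `coherence_peaks`, `behavior`, `probe`, exclusion `log`)
are in the report and can be written out with `write_report(rep, dir)`.
A thin CLI over the same functions lives at
`inst/scripts/thetamaze.R` (`simulate` / `analyze` subcommands).

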