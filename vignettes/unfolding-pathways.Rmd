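---
title: "Resolving metal-cluster unfolding pathways from simulated single-molecule pulling experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving metal-cluster unfolding pathways from simulated single-molecule pulling experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcespec)
library(dplyr)
```

## The problem

Metallothionein (MT) binds its metals in two polynuclear metal–thiolate
clusters, M4S11 in the C-terminal alpha domain and M3S9 in the
N-terminal beta domain. When a single MT molecule is stretched between an
AFM tip and a surface inside a (GB1)3–MT–(GB1)3 polyprotein, the clusters
rupture and the enclosed polypeptide segment is released, producing a
sawtooth force–extension curve. Each rupture adds a contour-length
increment

$$\Delta L_c = 0.36\,\mathrm{nm/aa}\times n_\mathrm{aa} - d_\mathrm{folded},$$

so the increment identifies *which* segment unfolded: 0.36 × 34 − 1.3 =
10.9 nm for the whole alpha segment (Cys34–Cys67), 0.36 × 25 − 1.2 =
7.8 nm for the beta segment. When the cluster breaks in two steps through
an intermediate that keeps one *anchoring cysteine* bound, the single
~11 nm increment splits into a pair summing to ~11 nm; the four resolvable
anchors define pathways P1–P4 with pairs (5.2, 6.1), (4.1, 7.2),
(3.2, 8.1) and (2.4, 9.3) nm. Because the larger sub-segment always lies
C-terminal of the anchor, the temporal order of the pair reveals the
unfolding direction: large-first means C-terminal-first.

`forcespec` implements the full analysis chain for such experiments —
worm-like-chain (WLC) branch fitting, increment extraction,
marker-fingerprint selection, pathway and direction classification, and
Bell–Evans dynamic force spectroscopy (DFS) — together with a kinetic
Monte-Carlo simulator that produces curves with known ground truth, so
that every stage of the analysis can be verified quantitatively without
instrument data.

## Models

### Polymer elasticity

Rising branches follow the Marko–Siggia WLC interpolation

$$F(x) = \frac{k_\mathrm{B}T}{p}\left[\frac{1}{4\,(1-x/L_c)^2} -
\frac{1}{4} + \frac{x}{L_c}\right]$$

with persistence length $p$ and contour length $L_c$. The persistence
length of unfolded polypeptide is not reported alongside most
experiments; we default to $p = 0.4$ nm and $k_\mathrm{B}T = 4.114$ pN nm
(298 K), typical polyprotein values, and fix $p$ during branch fits by
default: on short branches $L_c$ and $p$ are poorly identifiable jointly,
and a fixed $p$ makes increments comparable across branches
(`fit_persistence = TRUE` co-fits it when branches are long). The exact
functional form is encapsulated in `wlc_force()`; everything downstream
uses it through that interface.

### Rupture kinetics

Bond rupture under force follows the Bell model,
$k(F) = k_\mathrm{off}\exp(F\Delta x / k_\mathrm{B}T)$. At a constant
loading rate $r$ the rupture-force distribution has the closed-form
survival function used by `rupture_force_survival()`, a most probable
force linear in $\ln r$ with slope $k_\mathrm{B}T/\Delta x$, and an exact
inverse-CDF sampler (`sample_rupture_force()`). Published parameters used
as simulator inputs: $k_\mathrm{off} = 25$ s$^{-1}$ (Zn-alpha cluster),
10 s$^{-1}$ (Cd-alpha), 0.5 and 1.6 s$^{-1}$ for Zn/Cd rubredoxin-like
single-site controls; $\Delta x$ defaults to 0.20 nm for the cluster and
0.15 nm for the single site.

### The simulator

`simulate_curve()` performs a quasi-static constant-velocity ramp: at
each piezo position the force balances the WLC of the current total
contour length against the cantilever spring; every intact unit
accumulates hazard $k(F)\,\mathrm{d}t$ and ruptures when the accumulated
hazard crosses an exponential threshold (kinetic Monte-Carlo). Cluster
domains first draw a scenario from a `pathway_mixture()` — one-step with
probability 0.51, otherwise one of P1–P4 with probabilities
0.16/0.12/0.10/0.11 and C-terminal-first direction with probability 0.55,
the observed Zn-alpha statistics — and release their increments
accordingly; two-step intermediates reuse the domain kinetics by default,
reflecting the observation that all pathways occur with similar
frequencies and hence similar bond strengths. Measurement noise is
Gaussian on the recorded force only. Every curve carries a ground-truth
sidecar with the per-event scenario, pathway, direction, rupture force
and position.

## Instrument defaults and why they look the way they do

Instrument parameters are not part of the published analysis, so they are
package choices, set once by a pilot calibration and documented here:

| parameter | default | rationale |
|---|---|---|
| pulling speed | 6000 nm/s | see below |
| cantilever stiffness | 40 pN/nm | typical soft SMFS lever |
| force noise SD | 8 pN | typical deflection noise |
| sampling interval | 0.025 nm | 40 kHz-class acquisition at this speed |
| tether length | 5 nm | linkers/tags in series |
| detachment force | 300 pN | above the marker force range |

The pulling speed deserves explanation. With
$k_\mathrm{off} = 25\,\mathrm{s^{-1}}$ the cluster survives only ~40 ms
at zero force. At conventional slow ramps (hundreds of nm/s) most
clusters rupture while the force is still below any usable detection
threshold, and the second sub-step of a two-step event frequently follows
the first within less than the ~1 nm AFM length resolution. Both effects
destroy exactly the phenomenology the simulator exists to verify. At
6000 nm/s the cluster loads to ~100 pN (the measured one-step scale is
75 ± 34 pN, so this sits within one standard deviation), two-step
intermediates separate by several nm, and the effective loading rates
(~10^4–10^5 pN/s) stay inside the published DFS range of
10^3–3×10^5 pN/s.

Marker (GB1-like) domains are specified by their fingerprint — 18 nm
increment, ~180 pN — rather than by kinetic constants.
`calibrate_marker_kinetics()` inverts the most-probable-force relation at
the effective loading rate $k_\mathrm{eff} v$ (WLC and cantilever in
series, evaluated at the target force) and returns the matching
$k_\mathrm{off}$; with $\Delta x = 0.25$ nm this lands at
$k_\mathrm{off} \approx 0.12\,\mathrm{s^{-1}}$, a realistic value for a
mechanically stable fold. Two consequences of the physics are worth
knowing. First, six markers share the load, so the *first* marker
ruptures are weakest-link draws roughly
$(k_\mathrm{B}T/\Delta x)\ln 6 \approx 30$ pN below the single-domain
most probable force; simulated marker forces therefore centre near
140–150 pN with a staircase rising toward 180 pN, as in real polyprotein
curves. The marker force gate in the selection criteria (50 pN) sits
below this distribution because the 16–20 nm increment window, not the
force, is what identifies a marker. Second, because the WLC loading rate
is force-dependent, realized rupture-force modes sit somewhat below the
constant-rate Bell–Evans point prediction; the calibration targets the
latter.

## The analysis pipeline

`analyze_curve()` chains the stages:

1. **Baseline**: the zero-force reference is the median force over the
   detached tail at the end of the retraction — unlike the start of the
   curve, which is already under entropic load, the tail carries no
   force. Detection is invariant to constant force offsets.
2. **Peak detection**: a moving-average smoother (11 points; detection
   only, never fitting) and a running-maximum scan: a rupture is called
   when the smoothed force falls 15 pN below its running maximum, and the
   detector re-arms once the force rises half a threshold above the
   following valley. Peak positions and forces are then refined on the
   raw trace, because the smoothed maximum sits up to half a window early
   and is biased low by averaged post-rupture points. Peaks below 20 pN
   are discarded; the final peak is the detachment.
3. **Branch fits**: each rising branch (points above a 10 pN floor;
   at least 10 points) is least-squares fitted for $L_c$;
   the rupture force is re-estimated from the fitted WLC at the peak
   extension, which removes the noise bias of reading a single sample.
4. **Increments**: $\Delta L_{c,i} = L_{c,i+1} - L_{c,i}$. Negative or
   >25 nm increments are flagged artifacts (no construct segment is that
   long).
5. **Selection and attribution**: a curve is accepted when at least three
   peaks carry the marker fingerprint (increment in 16–20 nm, force
   ≥ 50 pN); remaining non-detachment peaks are attributed to the target
   domain. Rejection, and acceptance with an empty target list (apo
   controls), are normal outcomes.

`classify_event()` labels the target increments of each accepted curve:
a single increment in 10–13 nm is one-step; a pair summing to
11.3 ± 1 nm is matched, as a sorted pair, to the nearest pathway by
Euclidean distance (accepted within 0.7 nm, about half the AFM length
resolution; exact distance ties break deterministically toward the lower
pathway id and are flagged); the observed order then sets the direction
via `assign_direction()`, with a 0.2 nm resolution guard for near-equal
pairs. Events with more than two increments are counted as multi-step
and excluded from pathway statistics, mirroring their <1% incidence in
experiments. `tabulate_pathways()` produces the per-pathway counts and
frequencies, the N/C split, and the increment histograms (0.4 nm bins
for two-step, 1 nm for one-step).

### What recovery does and does not show

On noiseless data the round trip is exact: every visible rupture is
detected with its increment within 0.1 nm and no false peaks (the test
suite's observation-model oracle also predicts which truth events are
invisible — force below the floor, drop below the threshold, or closer
than the resolution to the previous peak — and how their increment rolls
into the preceding one). On noisy defaults the recovered mixture runs
about 2–5 percentage points rich in one-step events relative to the
generative 51%, because two-step events are harder to observe than
one-step events: ~3% merge below the length resolution and are counted
one-step (exactly as an instrument would count them), ~5% lose their
first sub-step below the 20 pN detection floor (the orphaned partner
lands in the unassigned bucket), and ~3% fail the pair tolerance under
fit noise. These are selection effects that real experiments share; the
package reports them rather than correcting for them. The direction
statistic is essentially unbiased (~55% C-terminal recovered from a 55%
input) because merging and detection losses act nearly symmetrically on
the two directions.

The simulator also does **not** emulate several features of real data:
baseline drift and slow force creep, adhesion peaks near the surface,
refolding during the ramp, correlated (1/f) noise, multiple tethers, or
more-than-two-step cluster ruptures. Passing recovery tests therefore
validates the analysis logic, not robustness to every instrumental
artifact.

## Dynamic force spectroscopy

`dfs_recovery()` reproduces the standard DFS protocol: rupture forces
sampled at the geometric centres of five log-spaced loading-rate bins
spanning 10^3–3×10^5 pN/s, a most-probable force per bin, and a linear
fit of $F^\ast$ on $\ln r$ giving $\Delta x = k_\mathrm{B}T/s$ and
$k_\mathrm{off} = e^{-a/s}/s$. The modal force uses a Gaussian KDE whose
bandwidth is Silverman's normal-reference value rescaled by $n^{2/35}$ —
from the $n^{-1/5}$ density-estimation rate to the $n^{-1/7}$ rate
optimal for mode estimation. The wider kernel roughly halves the
variance of the per-bin mode at the cost of a ~2 pN bias that is nearly
constant across bins; since the bins share one distribution shape, that
bias moves only the intercept, and the induced $k_\mathrm{off}$ shift is
well under 10%. With 300 events per bin the recovered $k_\mathrm{off}$ is
unbiased with a log-scale spread of ~0.15 (cluster parameters) to ~0.26
(single-site parameters, whose zero-force extrapolation is longer); the
geometric standard error reported by `fit_bell_evans()` reflects this
multiplicative error structure, and `autoplot()` draws the ×3/÷3
hypothetical-fit envelope as a sensitivity band.

Per-event loading rates from constant-speed curves
(`estimate_loading_rate()`) use the slope of force against time over the
last 20% of each branch, with time reconstructed from the cantilever base
position $z = x + F/k_c$; clocking by extension alone would overestimate
the rate by the tether-to-effective-stiffness ratio.

## Numerical choices and degenerate inputs

* `wlc_extension()` inverts the WLC by safeguarded Newton iteration to a
  1e-9 pN force residual; the simulator's force balance solves
  $x + F(x)/k_c = z$ the same way, vectorised over a whole branch.
* Branch $L_c$ fits are one-dimensional golden-section optimisations on
  the interval just above the branch's maximum extension; non-convergent
  or under-sampled branches are flagged and excluded rather than
  guessed.
* The beta domain ships with a one-step increment of 7.8 nm and an
  explicitly illustrative "unresolved split" two-step mode (uniform split
  point), because anchoring cysteines in the beta sequence are too close
  to resolve; beta events receive no pathway labels.
* Residue counts in `mt3_segment_table()` are stored exactly as
  published rather than derived from residue indices — the published
  counts mix endpoint conventions (Cys34–Cys67 = 34 aa but
  Cys45–Cys67 = 22 aa), and the table keeps the printed values while
  enforcing the $\Delta L_c$ identity through the folded distances.
* All randomness flows through R's global RNG; `simulate_dataset()`
  derives per-curve seeds from the master seed, so datasets are
  byte-reproducible.

## Problem sizes

The shipped tests verify the pipeline at the scales a desk study
supports: 800-curve mixture recovery and 400-curve direction recovery
(binomial 3-SE checks), 200 single-marker curves for marker fidelity
(mean increment 18.0 ± 0.2 nm), 40 noiseless curves for the exact round
trip, 10^5 samples for the sampler-vs-survival Kolmogorov–Smirnov check,
and 300-events-per-bin DFS recoveries. `scripts/acceptance.R` re-runs the
same experiments end to end from a single seed.

## A worked example

```{r example, eval = FALSE}
report <- run_pipeline("Zn-aMT", n_curves = 200, seed = 1)
report$statistics
glance(report$statistics)

sim <- simulate_curve(polyprotein_construct("Zn-aMT"), seed = 4)
events <- analyze_curve(sim$curve)
autoplot(sim$curve, events = events)

rec <- dfs_recovery(kinetic_parameters(k_off = 25, delta_x = 0.20))
tidy(rec$fit)
autoplot(rec$fit, events = rec$dataset)
```

## Known limitations

* Quasi-static force balance: cantilever dynamics, hydrodynamic drag and
  finite feedback bandwidth are not modelled, so very fast ramps are
  idealised.
* The one-step/two-step recovery carries the observation bias discussed
  above; comparisons against generative probabilities should use the
  matched tolerance (3 binomial SE) rather than expect exact equality.
* Only the TSV curve format ships; vendor AFM formats need external
  conversion.
* Pathway classification assumes the alpha-domain pair table; other
  proteins need their own `pathway_set()`.
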