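---
title: "Stochastic modelling of genome replication and IPLS inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modelling of genome replication and IPLS inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliscape)
```

## The model

`repliscape` models S phase of the human cell cycle as a stochastic
interaction between two limiting resources distributed over a genome binned
at 5 kb:

* **Potential origins** (licensed MCM double hexamers). Before each S
  phase, `N_PO = round(L / d_PO)` origins are drawn with replacement from a
  normalised per-bin probability vector, the *initiation probability
  landscape* (IPLS). The effective landscape is a mixture
  `(1 - r) * I(x) + r / n_bins` of a structured profile and a uniform
  "dispersed initiation" floor.
* **Firing factors**, a small pool of trans-acting activators
  (`N_F = round(rho_F * L)`, with `rho_F` in factors per Mb). Factors
  become available progressively after S-phase entry following
  `N_F (1 - exp(-t / tau))` with `tau = 60` min by default.

A free factor and a potential origin react bimolecularly with rate
constant `kon`: the total firing propensity is `kon * N_PO(t) * F_free(t)`.
A firing traps one factor and emits two forks that move apart at constant
speed `v` (1.5 kb/min). Forks passivate every unfired origin they sweep;
two converging forks merge (a termination) and release one factor; a fork
reaching a chromosome or gap boundary retires, and every two retired forks
release one factor. Because the firing regime is controlled by the product
`kon * L`, the package parameterises reactivity by the genome-size
invariant `kone = kon * L` (8.625 kb/min by default, which reproduces
`kon = 3e-6` per minute on the 2,875 Mb human autosomal genome). A desk
scale simulation of a 100 Mb genome therefore runs in the same kinetic
regime as a whole-genome one.

The event loop is an exact stochastic simulation over three event types:
candidate initiation (exponential waiting time at the current propensity,
redrawn after every event), the earliest deterministic fork encounter
(merge or boundary), and the next deterministic factor-arrival threshold
of the activation curve. Ties between an initiation and an encounter are
resolved in favour of the encounter so a recycled factor is accounted for
before the next propensity draw. Two numerical details are worth stating:
the passivation sweep of an event's fork advance is applied *before* the
firing choice of the same event (an origin overtaken during the advance
cannot fire), and the asymptotically-arriving last factor of the
activation curve is assigned the time at which the expected deficit drops
below one half (the floor of the activation curve never reaches `N_F` at
finite time).

Per-bin replication times and fork directions are reconstructed after the
event loop from the fired-origin list by a first-passage computation:
`rt(x) = min_i (t_i + |x - x_i| / v)`, with sign given by the side the
winning wave came from, and terminations located where left- and
right-moving waves meet. This is exact for constant fork speed.

## Observables

* **RFD** (replication fork directionality): per bin,
  `(n_R - n_L) / n_sims`; initiation and termination bins contribute 0.
* **MRT** (mean replication timing): the simulator records each bin's
  global replicated fraction at its own replication moment; these are
  mapped into 6 equal S-phase fractions (half-open intervals, last
  closed), and `MRT(x) = sum_i p_i(x) * i/6 + 1/12`, mimicking a
  six-fraction Repli-seq measurement. `compute_mrt_time()` returns the
  true mean replication time in minutes.
* **OE** (observed origin efficiency): the fraction of simulations in
  which at least one origin fired in the bin (binary per simulation).
* **Kinetics**: per-simulation T95/T99/T100 (ensemble medians), and the
  firing rate per unreplicated length `I(t)` in 5-minute windows, pooled
  across the ensemble (ratio of summed counts over summed unreplicated
  length). Windows where less than 1% of the pooled genome remains
  unreplicated are dropped: beyond that point the denominator consists of
  a handful of terminal gaps and the ratio no longer describes
  genome-wide kinetics.
* **RT variability**: per-bin interquartile range of replication time,
  by MRT decile. With the replicated-fraction proxy used by
  FACS-anchored measurements the curve is bell-shaped; with true time it
  increases monotonically — the package reproduces both behaviours,
  showing the bell to be an artefact of the non-linear time/fraction
  relation.

## MRT/RFD consistency and fork speed

Under constant fork speed, `RFD(x) = v * dMRT_t/dx`, hence over a window
of length `l`: `MRT_t(x+l) - MRT_t(x) = (l/v) <RFD>`. Pointwise
derivatives of noisy data are unstable, so `mrt_rfd_consistency()` works
at a set of window lengths, fits a through-origin least-squares slope
(the relation has no intercept), and reports `v_est = l / slope` and the
Pearson correlation per scale. MRT is converted from fraction to minutes
by multiplication with an assumed S-phase duration; the true
fraction–time relation is sigmoid rather than linear, which slightly
distorts the extremes of S phase — a known approximation, not modelled.
Windows advance by one bin and any window touching missing or masked data
is excluded.

## Closed-form origin-strength estimators

Ignoring passivation, a bin carrying `n(x)` potential origins has fired by
time `t` with probability `A_x(t) = 1 - exp(-kon n(x) int_0^t F_free)`.
Because a 5 kb bin is far more often passivated by incoming forks than
internally fired, its mean passivation time is close to its MRT, so
`OE(x) ~ A_x(MRT_t(x))` (`predicted_oe()`). Inverting this relation with
`OE ~ dRFD/2` yields a per-bin potential-origin estimator
(`estimate_n()`), and three landscape estimators (`ipls_from_data()`):
the full availability-integral form, a constant-free-factor
approximation proportional to `1/MRT`, and an empirical exponential form
`dRFD * exp(-6 MRT)` whose decay constant absorbs the late-S rise of
free-factor availability as termination events return factors to the
pool. The exponent 6 is an empirical constant and is exposed as a
tunable argument.

`delta_rfd()` smooths RFD with a 15 kb running mean, takes backward
differences between consecutive bins, clips negative increments, and
(for the estimators) keeps the top 15% of values. Peak detection for
initiation-zone calls runs on the *unthresholded* increments —
thresholding first would turn broad peaks into cliff-edged plateaus and
distort the width criterion. The backward-difference assignment keeps
detected increment maxima aligned with the OE maxima of the simulations
(a forward assignment shifts calls one bin left). `detect_izs()` retains
local maxima at least 0.02 high and at least 4 bins wide, with width
measured at half prominence — the dominant convention of the common
scientific peak finders, which the implementation reproduces (it is
validated to 1e-7 against an independent reference in the test suite).

## The iterative inverter

The inversion of MRT + RFD into an IPLS alternates four steps:
calibration of `(rho_F, r)` by grid search (objective: MRT correlation at
10 kb plus RFD correlation at 5 kb, against experiment; fork speed and
`d_PO` barely move the profiles and stay fixed), ensemble simulation
under the current landscape, training of a convolutional network to
predict the effective landscape at the centre of a sliding MRT/RFD
window from the *simulated* pair, and application of the trained network
to the *experimental* pair to produce the next landscape. The initial
landscape comes from RFD increments (50 kb smoothed, 80th percentile
threshold) — a flat initial landscape carries no positional signal and is
rejected. Iteration stops at the requested depth or after two
consecutive score decreases; the best-scoring landscape is returned.

The network has three valid-mode conv layers (kernel 10, 15 filters,
ReLU, 1% dropout each), pairwise max pooling, and a dense sigmoid
read-out; it is trained with binary cross entropy and Adadelta
(rho = 0.95). Since no deep-learning framework is available to R in this
project's dependency set, the network is implemented directly with BLAS
matrix operations: convolutions run once per chromosome and windows
gather shared features, which makes full-batch training cheap at desk
scale. Choices the interface leaves open and how they were resolved:

* *Target scaling*: the sigmoid output is trained on the effective
  landscape divided by its maximum over the training chromosomes; the
  constant cancels in the final renormalisation.
* *Augmentation*: each epoch, 1% of raw RFD bins are re-assigned uniform
  values in [-1, 1] before the 50 kb input smoothing; targets are never
  perturbed.
* *Early stopping*: validation loss on a held-out chromosome, patience 5
  (the package default; tests use 10), at most 100 epochs.
* *Chromosome split*: by default the last chromosome is held out for
  testing and the second-to-last for validation; the split is an explicit
  argument because a fixed human-karyotype split does not transfer to
  small synthetic genomes (at least three chromosomes are required
  otherwise).
* *Window size*: 401 bins (2005 kb) by default; closed-loop tests use 101
  bins, which at synthetic-landscape scales loses little context and
  trains several-fold faster.
* *"Predict I + r"*: interpreted as the mixture target
  `(1 - r) I + r/n_bins`, consistent with the model's landscape
  decomposition, rather than as a separate scalar output.

On synthetic ground truth (24 Mb, three chromosomes), the closed loop
improves the joint score monotonically over 3 iterations and reaches MRT
correlations above 0.9 and RFD correlations above 0.8 against the held
"experimental" pair, recovering the generating factor density exactly or
to a neighbouring grid point; this is asserted in the test suite.

## The synthetic landscape generator

The generator emulates the measured structure of inferred human
initiation landscapes so the whole pipeline runs without downloads:

* flat-topped initiation zones (error-function edges of 10 kb), because
  initiation inside a zone is internally dispersed rather than
  point-like;
* a Poisson areal density of 3.5 zones per Mb, the areal density of RFD
  upshifts in human cells;
* log-normally dispersed widths around 60 kb and exponential relative
  strengths, so the strongest per-bin initiation frequencies approach the
  largest per-bin RFD upshifts seen in data (~0.14 per bin on the
  default fixture against ~0.17 reported on real profiles);
* a uniform floor carrying 20% of the mass, leaving ~80% of the
  landscape on 15–20% of bins (18% measured on the default acceptance
  fixture).

Default desk scale is 2–4 chromosomes of 25 Mb. With the reference
parameters this replicates in a median T95 of ~690 min, inside the
600–800 min band expected for the regime `T_S ~ 1/(2 v rho_F)` with
progressive factor activation.

What the generator does *not* emulate, and what that implies for the
in-model validation anchors:

* **A spatially structured floor.** Real inferred landscapes thin out in
  late-replicating DNA (potential-origin spacing grows several-fold in
  the latest decile); the synthetic floor is strictly uniform. Late in S
  phase, free factors accumulate while the per-unreplicated-length origin
  density stays at the floor value, so the firing rate `I(t)` remains
  elevated longer than on an inferred landscape: the measured `I_max` on
  the default fixture is ~0.03 per Mb per min, above the 0.01–0.02 band
  reported for whole-genome landscapes, with the mid-S shoulder of the
  curve inside that band.
* **Termination-free zones.** Converging outside forks can meet inside a
  passively replicated synthetic zone (~11% of zone-bin events), which
  depresses the RFD upshift relative to the counted efficiency; together
  with the 15 kb smoothing this puts the through-origin slope of OE on
  dRFD/2 near 1.2 rather than slightly below 1.
* **Ensemble-mean availability.** Evaluating the closed-form efficiency
  at the ensemble-mean MRT with the mean free-factor trace underestimates
  the mean of per-replicate availability integrals (the integral is
  convex in the replication time, whose per-bin spread is hours), so the
  counted-vs-predicted slope at zones exceeds 1 by several tens of
  percent at this scale; with per-simulation traces and times the slope
  falls to ~1.14 and the correlation rises to ~0.84.

These limits are inherent to the synthetic study conditions; the
estimators themselves are exact inverses of each other, which the test
suite asserts to machine precision.

## Numerical and edge-case conventions

* Coordinates are 0-based half-open in all files; internal bin `i` of a
  chromosome covers `[i*5000, (i+1)*5000)`. Partially covered bins
  receive coverage-weighted means (bedGraph) or summed coverage (BED).
* Data gaps longer than 1.5 Mb in any input profile are masked with
  500 kb flanks; before profile comparisons shorter gaps are masked with
  the same flanks. Missing and masked are distinct states: a missing bin
  may be filled by smoothing only when at least half its window carries
  data.
* Smoothing windows are centred running means truncated at chromosome
  ends and gap edges; masked bins never contribute.
* Origins sharing a bin sit at the bin centre, so the first firing in a
  bin passivates the bin's remaining origins.
* A segment that drew no potential origins can never replicate and is
  reported as an error naming the segment; with the default floor its
  probability is negligible.
* All randomness flows through R's RNG; ensembles seed each simulation
  index separately, so results are independent of batching.

## Problem sizes

The test suite uses 24–100 Mb genomes with 8–200 simulations per
ensemble and a 101-bin inverter window; the bundled acceptance analysis
uses a 100 Mb genome with 200 simulations. These sizes keep every
analysis in the regime set by `kone` while completing in seconds to a
few minutes on one CPU.
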