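---
title: "A whole-brain neural mass model of interictal spike-wave EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-brain neural mass model of interictal spike-wave EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`spikewave` simulates scalp EEG from a whole-brain network of neural mass
models and quantifies how closely a simulated recording reproduces the
interictal epileptiform discharges (IES) of a reference recording. Its
intended use is in-silico epilepsy modelling at the region level: placing an
epileptic parameter regime in candidate cortical regions, scoring the
resulting scalp EEG against a reference, fragmenting a region to refine the
epileptogenic-zone (EZ) extent, and verifying by virtual resection that the
scalp spikes disappear. Everything runs on synthetic geometry, connectivity
and reference data, so no clinical recordings are required anywhere in the
pipeline.

## The neural mass model

### Single column

Each cortical region is a six-subpopulation neural mass: two glutamatergic
pyramidal pools (PYR and the collateral-excitation pool PYR2) and four
GABAergic interneuron classes — PV (fast somatic inhibition), SST (slow
dendritic inhibition, expressed through two kernels with slower apical and
faster basal kinetics), VIP (disinhibition of SST) and NGFC (very slow
volume inhibition). Each subpopulation converts its net membrane potential
$v$ into a mean firing rate through the sigmoid

$$S(v) = \frac{2 e_0}{1 + e^{r (v_0 - v)}},$$

with $e_0 = 2.5\ \mathrm{s^{-1}}$ (half the maximum rate), stiffness
$r = 0.56\ \mathrm{mV^{-1}}$ and half-activation potential $v_0 = 6\
\mathrm{mV}$. Every directed connection carries an alpha-kernel synapse,

$$\ddot y = \frac{W}{\tau_w} u(t) - \frac{2}{\tau_w} \dot y -
\frac{y}{\tau_w^2},$$

whose impulse response $h(t) = (W/\tau_w)\, t\, e^{-t/\tau_w}$ peaks at
$W/e$ at $t = \tau_w$; $W$ (mV) is the average synaptic gain and $\tau_w$
(s) the PSP kinetics. The input $u$ is the presynaptic rate scaled by a
dimensionless coupling coefficient $C$. Membrane potentials are signed sums
of the incoming PSPs. Only the synaptic inputs onto the layer-V pyramidal
pool contribute to the regional current dipole, so the PYR membrane
potential is the dipole-drive trace every downstream stage consumes.

Units are mV, seconds and spikes/s throughout.

### Parameter defaults and presets

The supplementary parameter tables of the source model are not available,
so defaults follow the classical neural-mass literature: glutamatergic EPSP
$W = 3.25$ mV / $\tau_w = 10$ ms, fast PV IPSP $22$ mV / $5$ ms, slow SST
dendritic IPSP $10$ mV with $20$ ms apical vs $12$ ms basal kinetics, NGFC
slowest at $60$ ms. The excitatory loop couplings (135/108) and the
interneuron drive couplings (33.75) are the canonical values of that
literature; the slow dendritic DC gain is split over the apical and basal
kernels so their sum reproduces the canonical slow-inhibition loop. All
defaults live in `inst/extdata/presets.json` and every number is
overridable per connection.

Five presets are shipped (`column_presets()`); all non-background presets
are multiplicative deltas on background:

* `background` — the resting operating point: low drive (noise mean 90
  spikes/s), fluctuations of a few mV with a low-frequency-dominated
  (1/f-like) spectrum and no narrowband peak above 8 Hz.
* `fcd_spikewave` — the epileptic regime: glutamatergic gain x1.9, PV
  somatic gain x1.3, SST dendritic gain x0.25, plus fine-tuning of the
  intra-column connectivity (a strengthened slow NGFC loop, x9/x4.5 on its
  couplings, and x2.4 on the noise coupling). The direction of the gain
  changes (more excitation and somatic inhibition, much less dendritic
  inhibition) is the physiological signature of type-2 focal cortical
  dysplasia tissue; the magnitudes and the connectivity fine-tuning were
  calibrated once so the column discharges 2–3 spike-wave complexes per
  second, and then frozen. The resulting complexes are a sharp ~+33 mV
  spike followed by a slow negative wave.
* `alpha_boost` / `beta_boost` — raised SST dendritic gain (x1.3) and
  raised PV somatic gain/coupling (x2.2/x4.0) respectively. Both presets
  also raise the noise mean to 220 spikes/s: in situ, the occipital and
  frontal columns expressing these rhythms receive continuous network
  afferents; when a preset is simulated as an isolated column, the raised
  drive stands in for that input. With it, the dominant spectral peak
  lands in the alpha (8–12 Hz) and beta (13–30 Hz) bands; both arise from
  the loop resonances of the respective interneuron classes (the
  10 + 20/12 ms SST loop resonates near 10 Hz, the 10 + 5 ms PV loop above
  13 Hz).
* `delta_boost` — PSP kinetics of the main loops slowed (all main
  $\tau_w$ x2), moving the dominant peak into the delta band. The verbal
  recipe in the source describes "decreasing the time constant"; slowing
  (increasing $\tau_w$) is the only direction that produces delta, so the
  phrase is read as "slowing the kinetics".

### Thalamus

A single lumped thalamic mass models the thalamocortical relay pool (TC,
glutamatergic) and two reticular-nucleus pools (RN1 slow, RN2 fast
GABAergic, both inhibiting TC). Cortical afferents excite all three pools,
TC excites both RN pools, and the TC output rate is broadcast back to the
cortex. Per-hemisphere thalami are not modelled.

## The whole-brain network

The default atlas holds 66 cortical regions (Desikan–Killiany labels,
insula excluded, 33 per hemisphere) plus the thalamus: 67 masses. Regions
are coupled by long-range glutamatergic projections that originate from the
PYR pool and terminate on PYR, PV, SST, VIP and NGFC of the target column
(a single shared weight per target class); thalamic output reaches the same
five classes, and every cortical region projects onto TC, RN1 and RN2.
Cortico-cortical weights are the structural connectivity matrix normalised
to unit maximum and multiplied by a single global coupling gain (default
15, chosen so the coupled background stays stationary while an epileptic
region measurably perturbs its afferent targets). Conduction delays are
centroid distances divided by 7.5 m/s, rounded to the nearest integration
step (error at most dt/2) and implemented with a ring buffer; times before
the simulation start use the resting output rate of each mass.

Numerics: the whole system (each synapse a $(y, \dot y)$ pair) is advanced
with a fixed-step stochastic Heun scheme at dt = 1/2048 s, with the
Gaussian white rate noise held constant across the two stages of a step.
The per-step noise SD is scaled by $1/\sqrt{dt}$ so the noise spectral
density — and hence the dynamics — is invariant to the step size; the `sd`
parameter is therefore a white-noise intensity (spikes/s/$\sqrt{Hz}$).
For a constant input the discrete fixed point of the scheme is exactly the
continuous equilibrium $y = W \tau_w u$. Each region's noise stream is
seeded with `seed + region_index`, which makes an isolated column ("region
1" of a one-mass network) bit-identical to the same region inside a
fully decoupled network — the property the decoupled-limit tests assert
exactly. The first 2 s of every simulation are discarded before any
analysis. A numerical blow-up (non-finite or absurdly large state) raises
an error naming the region and step.

## Forward model

Scalp potentials use the current-dipole approximation: a source with
summed layer-V drive $y_k(t)$ carries the axial current $I_k(t) = \eta
y_k(t)$ with $\eta = 10^{-3}$ S, and contributes
$\frac{1}{4 \sigma \pi} I_k \|d_k\| \cos\theta_k / R_k^2$ at an electrode
at distance $R_k$, where $\theta_k$ is the angle between the dipole
orientation and the source-electrode axis and $\sigma = 0.33$ S/m.
The synthetic leadfield is this formula evaluated for one
normal-constrained, radially oriented dipole per region centroid
(single-shell homogeneous conductor); a dipole-level matrix from a BEM
computation can be aggregated to regions with `aggregate_leadfield()`
(rows of dipoles sharing a region are summed, exactly as a brute-force
group sum). Projection is linear; `virtual_resection()` zeroes the rows of
resected regions, preserving dimensions so traces stay aligned.

A single global scale (`scalp_scale_default()`, 8.5e3) maps model units to
microvolts. It was fixed once so that an all-background whole-brain
simulation spans roughly 10–50 uV peak-to-peak on the bipolar derivations
— a plausibility calibration of this package, not an empirical claim.
Electrodes are a 32-channel 10–20-based layout on a 92.5 mm scalp shell;
the region centroids sit on a 72 mm cortical shell (uniform source depth —
hand-placed anatomical centroids gave occipital sources a 5-fold leadfield
advantage purely through depth, which is a geometry artifact, not
physiology). Region fragmentation places children along the parent's
anteroposterior axis and re-projects them onto the parent's shell radius
for the same reason.

## Spike detection and the similarity indices

### Single-channel index

`xcorr_similarity()` removes each signal's mean, scales by the product of
their norms, and returns the maximum over lags of the cross-correlation
$R(l) = \sum_n f_n g_{n+l}$ — 1 for identical signals regardless of
amplitude scale or a pure time shift. One boundary subtlety: against a
sign-flipped copy the maximum over all lags equals the negated minimum of
the autocorrelation, which is greater than -1 for any non-degenerate
signal; the index reaches -1 exactly only when the lag search is confined
to the matched alignment (`max_lag = 0`). Both modes are exposed; the
unrestricted maximum is the default because it keeps the index high when
matching discharges are not concomitant. Near-maximal lags found by the
FFT evaluation are re-evaluated with exact dot products so that the
self-similarity of a signal is exactly 1.

### Spike detector

The detector band-passes each channel to 1–40 Hz (zero-phase FFT filter
with raised-cosine transitions; no IIR design dependency exists in this
stack) and computes a spike-emphasis trace in 6–30 Hz, where spike energy
concentrates and 1/f background energy does not. A sample seeds an event if
its absolute emphasis amplitude exceeds `k` scaled MADs (default k = 4) of
the detection statistic and its broadband amplitude exceeds an absolute
floor (default 30 uV, a clinical-style minimum for scalp spikes; lower it
for source-level traces). The MAD reference is the median of the
per-channel MADs over the whole recording: a channel carrying a
*continuous* 2–3/s discharge has no quiet baseline of its own, and judging
it against its own statistic suppresses exactly the spikes one wants to
find — referencing the recording mimics how a reader compares a channel
against the background of the whole page. Events are separated by a 200 ms
refractory period, measured (min/max/peak) in a 600 ms window, and
labelled by `label_polarity()`: first letter the sign of the spike
extremum, second the sign of the dominant post-spike deflection of the
< 8 Hz component (the documented fallback when no clean wave exists).
With `k = 0` the detector degrades to a plain absolute-threshold detector.

On the calibrated synthetic world these defaults give recall 1 / precision
1 on noise-free injected trains, recall above 0.9 at SNR 5, zero false
alarms on coupled background simulations, and stable detection of the
epileptic regime's scalp projection.

### The seven-criterion scalp score

`eeg_ies_score()` compares two feature sets extracted by `ies_features()`
over a 40 s window (per derivation: event rate, dominant polarity class,
mean absolute spike amplitude, presence; per EEG: highest-amplitude
derivation, amplitude rank order along each anterior-to-posterior chain,
and the phase-inversion electrode — the common electrode of an adjacent
derivation pair with dominant polarities PN above and NP below, the most
prominent such pair by summed spike amplitude, ties to the more anterior).
The weights are 1 point for the highest-amplitude derivation, 5 for the
amplitude gradient (all chains must match; rank ties average), 5 for the
phase-inversion electrode, and 1 point per derivation for each of rate
agreement (within +/-50% of the reference rate; matching emptiness when
the reference rate is zero), polarity agreement (matching emptiness
counts), and presence/absence-pattern agreement (criteria 5 and 6 judge
the same channel-wise set identity from the presence and the absence
side). The total is normalised by the theoretical maximum
$11 + 4 n_{derivations}$ and expressed in percent. A reference EEG with no
spikes anywhere scores 0 by convention.

Two design notes. First, the criterion-wise award rules were chosen so
that a feature set scored against an identical copy reaches exactly 100%
for any derivation count — the defining identity of the score — which
forces vacuous agreement (both sides spike-free) to count on the
per-channel criteria. Second, with these rules a pair earning *only*
criteria 1 and 7 cannot arise from real feature sets (the
highest-amplitude agreement forces presence agreement on that channel);
the 6/31 = 19.4% tally for that combination is therefore exposed through
the normalisation helper `ies_tally()` and verified there.

## The synthetic world, and what a green test establishes

`make_synthetic_head()`, `make_synthetic_connectivity()` and
`make_reference_eeg()` emulate the inputs that are clinical in origin and
cannot be shipped: spherical-shell geometry with named anatomically-placed
(but synthetic) centroids, exponential distance-decay connectivity with
35% density, and reference recordings of pink noise plus injected
spike-wave templates (difference-of-Gaussians spike of 70 ms followed by a
half-sine wave of 300 ms — deliberately independent of the neural mass
model, so detector round-trip tests are not circular). Injection times sit
on a jittered regular grid inside the analysis window, so `floor(rate x
duration)` events are always present and never closer than the detector's
refractory period. Every generator is deterministic per seed.

What the generators do *not* emulate: folded cortical geometry and
orientation disorder, skull/scalp conductivity layering (a BEM), spatially
correlated sensor noise, artifacts, and the morphological variability of
real discharges. A green EZ-recovery test therefore establishes that the
pipeline is self-consistent — that region identity and extent are
recoverable from scalp-level scoring alone *within the model's own
physics* — not that the method localises real lesions; the latter claim
would need clinical data this package deliberately does not contain.

`replay_fcd_scenario()` chains the full workflow: reference generation
from a known EZ, placement search over all candidate regions (descending
score, ties by candidate order), optional fragmentation into surface
fractions whose children keep the parental connectivity, paired
full-region vs sub-fraction scoring, and virtual resection with a
post-resection spike count. On the default synthetic world the true region
wins the 66-region search decisively (100% vs 83% for the runner-up), the
sub-fraction EZ outscores the full region whenever the reference came from
the sub-fraction, and resection removes every detected scalp spike.

## Known limitations

* The epileptic regime is one calibrated operating point; the package does
  not explore the full bifurcation structure of the column.
* Propagation at the default coupling is deliberately weak (sub-threshold
  perturbation of afferent targets); stronger coupling in this circuit
  recruits the interneuron classes of the target columns and produces
  surround inhibition rather than propagated spikes, so spike diffusion
  patterns seen clinically are only partially reproduced.
* The EDF codec covers the subset of the format the package writes
  (16-bit, equal rates, 1 s records); it is not a general EDF(+) reader.
* Scalp amplitudes rest on a single global calibration constant; absolute
  microvolt values are plausible, not subject-accurate.
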