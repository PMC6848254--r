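---
title: "Neural-mass networks as generic change detectors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-mass networks as generic change detectors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(devmass)
```

`devmass` simulates networks of reciprocally coupled excitatory/inhibitory
neural-mass nodes and studies when such a network acts as a *local change
detector*: a unit that responds transiently whenever a neighboring,
stimulus-driven representation changes abruptly.  One framework covers
cortical On/Off responses, distinct onset/offset frequency receptive
fields, the omitted-stimulus response (OSR) and the sequence mismatch
negativity (MMN).  This vignette describes the model, its parameters, the
design decisions behind each experiment, the numerical choices, and the
known limitations.

## The population model

Each node contains one excitatory (E) and one inhibitory (I) population.
A population converts incoming firing rate to post-synaptic potential by
convolution with a synaptic kernel

$$h_c(t) = \frac{H_c}{\tau_c}\, t\, e^{-t/\tau_c}\,\Theta(t),$$

equivalently the pair of first-order ODEs solved by the integrator:
$\dot v = u$, $\dot u = (H_c/\tau_c)\,x - (2/\tau_c)\,u - v/\tau_c^2$.
The kernel peaks at $t=\tau_c$ with height $H_c/e$ and has DC gain
$H_c \tau_c$.  Potential converts back to rate through the logistic
sigmoid $S(v) = 2 e_0 / (1 + e^{r (v_0 - v)})$, half-maximal at the
threshold $v_0$ and saturating at $2 e_0$.

Defaults (`synapse_params()`, `sigmoid_params()`): excitatory kernel
$H_e = 3.25$ mV, $\tau_e = 10$ ms; inhibitory kernel $H_i = 22$ mV,
$\tau_i = 20$ ms; sigmoid $e_0 = 2.5$ spikes/s, $r = 0.56$ /mV,
$v_0 = 6$ mV.  All internal units are SI (seconds, spikes/s, mV) because
the $1/\tau^2$ term makes mixed units error-prone; constructors accept
seconds.

## Nodes and networks

`network_config()` assembles $N$ nodes and $M$ input channels from four
$N \times N$ non-negative gain matrices (`W_EE`, `W_IE`, `W_EI`, `W_II`;
element $[j,k]$ couples node $k$ into node $j$), external weights `W_EX`
(onto E) and `W_IX` (onto I, default $0.5\,W_{EX}$), and a constant
background drive $B$ to every excitatory population.  The standard single
node (`default_node_config()`) uses intra-node gains
$135 \times (0.8, 0.6, 0.2, 0.05)$, external weights $220 \times (0.2,
0.1)$ and $B = 220 \times 2.5 = 550$ spikes/s.  Synaptic kernels may
differ per node, which is how oscillator banks are built.

Two optional plasticity processes modulate the weights:

* **Adaptation** (`adaptation_params()`): every E-to-E connection carries
  an efficacy $a \in [0,1]$ with
  $\dot a = (1-a)/\tau_a - \kappa\, a\, m_{\text{pre}}$
  ($\tau_a = 200$ ms, $\kappa = 2$; fixed point $a^\ast = 1/(1 +
  \tau_a \kappa m)$, i.e. $0.5$ at 2.5 spikes/s).  External drive is
  never adapted.  `simulate_network(adapt_mask =)` can restrict
  adaptation to a subset of connections.
* **Short-term plasticity** (`stp_params()`): for node pairs inside a
  designated bank, the E-to-E gain relaxes toward
  $g\,\eta\,\alpha_{jk}\max(\mathrm{Cov},0)$ and the I-to-E gain toward
  $g\,\eta\,\beta_{jk}\,|\min(\mathrm{Cov},0)|$, where $\mathrm{Cov}$ is
  the trailing-window covariance (window $\Delta t = 200$ ms; defined as
  zero until one full window of history exists) of the pair's excitatory
  rates, $\eta = 0.05$, and $\alpha, \beta$ are Gaussian masks over node
  index distance (widths $0.2 N_b$ and $0.4 N_b$).  Because every other
  gain in the standard configuration is a multiple of the global scale
  135, the rule's targets are expressed on that scale through the factor
  $g$ (`gain_scale`); with raw gains the fixed points (at most
  $\eta\,\mathrm{Cov} \approx 0.3$) would be negligible against
  couplings of order $10$--$100$.  The decay side of the rule is read as
  a relaxation with time constant `tau_w` (default 1 s; the oscillator
  bank uses 0.3 s), keeping weight dynamics slow relative to the
  oscillation cycle.  Weights are updated every solver step.

## Integration

`simulate_network()` uses a fixed-step explicit 4th-order Runge-Kutta
scheme, default `dt = 0.5` ms, far below the fastest synaptic time
constant (10 ms); halving the step changes trajectories at the expected
4th-order rate on smooth problems.  Stimuli are stored as
piecewise-linear breakpoint functions and sampled exactly at the half
steps the RK4 stages need.  Integration starts from the all-zero state
and runs through a discarded *settle* interval (default 2 s) so reported
windows sample the attractor; identical inputs give bit-identical
trajectories.  Non-finite states abort with a diagnostic naming the node
and time.  The batched two-node scan kernel performs the same arithmetic
per grid point as an individual simulation, so batch and single runs
agree to round-off.

With these intra-node gains the isolated node has an oscillation onset
near $B \approx 115$ spikes/s: quiescent below, limit-cycle oscillation
(about 9.7 Hz at $B = 550$) above, saturating again beyond
$B \approx 650$.  At the standard operating point the limit cycle spans
nearly the whole sigmoid range, so firing-rate maxima sit close to the
5 spikes/s ceiling.

## Response categorization

`categorize()` labels a detector trace $m^E_2(t)$ around a 2-s stimulus
into $\{\text{Inc},\text{Dec}\} \times
\{\text{None},\text{On},\text{Off},\text{OnOff}\}$ plus `others`, from
maxima over five windows (seconds relative to onset): pre-onset
$[-0.5,0]$, post-onset $[0,0.5]$, pre-offset $[1.5,2]$, post-offset-1
$[2,2.5]$ and post-offset-2 $[3.5,4]$.  Metrics: $\Delta m_{\rm PrePost} =
|{\max}_{\rm pre-onset} - {\max}_{\rm post-offset-2}|$ (bistability is
direction-agnostic, hence the absolute value);
$\Delta m_{\rm Stim} = {\max}_{\rm pre-offset} - \max$ of *both*
baselines (conservative and symmetric); $\Delta m_{\rm On}$ and
$\Delta m_{\rm Off}$ compare the post-edge window to the window before
the edge.  Thresholds: bistable (hence `others`) if
$\Delta m_{\rm PrePost} \ge 0.1$; Inc if $\Delta m_{\rm Stim} > 0$; On /
Off flags if their deltas exceed 0.5 spikes/s.  A perfectly flat trace is
`Dec-None`; non-finite traces are `others`.  Raw rates are classified (no
envelope extraction): window maxima already absorb the oscillation.

## Connection-grid scans

`enumerate_grid()` spans all eight inter-node gains of the two-node
detector circuit: E-to-E and E-to-I in $135\times\{0,0.1,\dots,0.5\}$,
I-to-E and I-to-I in $135\times\{0,0.1,0.2\}$, both directions free
($6^4 \cdot 3^4 = 104{,}976$ points; a `"4d"` switch fixes the reverse
direction at zero for sensitivity analyses).  `run_scan()` integrates
every point (settle 2 s, stimulus on $[0,2]$ s, record to 4 s) in a
batched compiled kernel and classifies the detector trace.  Four
conditions (`scan_condition()`): I default; II no stimulus input to
inhibitory populations ($W_{IX}=0$); III NMDA-antagonist emulation,
inter-node E-to-E gains $\times 0.75$ and E-to-I gains $\times 0.5$; IV
adaptation on all E-to-E connections.  Condition III deliberately leaves
the intra-node gains untouched: reducing them saturates the isolated
node at the standard background drive and abolishes all responses, which
contradicts the condition's purpose of probing the detector repertoire
of a still-functional node.  `contingency()` cross-tabulates labels
between conditions in percent of all scanned points.

The full grid takes tens of minutes per condition on one CPU; the test
suite therefore evaluates the conditions on a fixed 4000-point uniform
subsample, whose type percentages estimate the full-grid values to a few
relative percent.  The package's own full-grid run is regression-locked
by a 200-row frozen fixture.

**Limitation.**  Within this implementation of the stated equations
(verified against an independent `deSolve` integration to $10^{-5}$),
several aggregate scan contrasts that have been reported for this class
of model do not reproduce: zeroing $W_{IX}$ *increases* rather than
decreases the count of Off-type solutions, adaptation increases Off- but
not On-type counts, and the Dec-On / Dec-OnOff families are not realized
under condition I at all.  The acceptance tests compute these counts and
leave the corresponding assertions failing rather than adjusting them.
The likely causes are unstated details of the original study
(initialization and attractor selection, settle duration, the exact
level-change arithmetic) interacting with the fact that at $B = 550$ the
node's limit cycle rides the sigmoid ceiling, which compresses the
margins that define Inc- and On-type labels.

## The four experiments

**On/Off survey** (`example1_onoff()`): scan plus one re-simulated
exemplar trace per realized type.

**Onset/offset receptive fields** (`example2_frf()`): a fixed Off-type
weight setting; per simulated tone the stimulus reaches node 1 (the
surround) with weights $(44, 22)\times ratio_1$ and node 2 (the recorded
cell) with $(44, 22)\times ratio_2$.  The shipped ratio table
(`frf_ratio_table()`, `inst/extdata/frf_ratios.csv`) emulates a
tonotopic gradient: the surround dominated by low tones, the cell's
direct input peaked at higher tones.  Rows with $ratio_1 = 1, ratio_2 =
0$ reproduce suppression-with-offset-peak; onset responses emerge as
$ratio_1$ falls.

**Omitted-stimulus response** (`build_bank()`, `example3_osr()`,
`osr_boundary()`): the periodicity of a pulse train is held by a bank of
$N_b = 21$ nodes whose resonance periods span 50--200 ms (linearly in
period, strictly monotone in node index).  Design choices, all the
package's own since only "different time constants" is prescribed for
such banks:

* Bank nodes are time-rescaled copies of the standard node (times scaled
  by $s_j$, gains by $1/s_j$, preserving DC gain) operated just *below*
  the oscillation onset ($B_{\text{bank}} = 114$): each node is then a
  high-Q damped resonator (ringing decays about 15% per cycle) with a
  measured reference period of 153 ms (`damped_period()`), and the whole
  bank is noiseless and phase-locks reproducibly to the train.  A
  resonant train builds up node ringing selectively (several-fold above
  off-resonant nodes); short-term plasticity (gain scale $67.5 = 135/2$,
  `tau_w` 0.3 s) binds the co-resonating group sub-critically, so the
  group resonance outlives the train by a few hundred milliseconds and
  then collapses -- the memory of the periodicity and its loss.
* The stimulus reaches bank nodes with $w_{EX} = 40$ and $w_{IX} = 0$;
  routing drive only to E makes the mean bank activity rise with
  stimulation, which the detector reads.
* The change detector is a $4.12\times$ slowed standard node at
  $B = 550$ (supercritical, so it free-runs at rest -- the source of
  trial-to-trial variability beyond the resonance range).  The bank's
  excitatory populations project onto its inhibitory population with a
  bank-total gain of 270: during any continuously-driven or resonant
  train the detector is quenched; its slow kernels integrate over the
  ring troughs, and while quenched the adaptation of its recurrent
  excitation (restricted to that one connection via `adapt_mask`)
  recovers.  When the sustained resonance collapses the detector fires a
  single over-shooting rebound burst -- the OSR -- which is why the
  simulated OSR can exceed the entrained response.  The time-scale
  factor 4.12 places the detector's period between integer multiples of
  the SOA grid, avoiding spurious subharmonic locking.
* The simulated MEG weights 0.7 on the detector and spreads the rest
  over the bank; the OSR peak is detected on the baseline-subtracted RMS
  envelope (130 ms window) of that signal within 0.5 s after the due
  time, with near-equal peak heights (within 15%) resolved in favor of
  the earliest.

Omission trials vary the train length over
$\max(8, \lceil 1\,\mathrm{s}/\mathrm{SOA}\rceil) + 0..7$ pulses, so at
least a second of entrainment precedes the earliest omission.  Below the
slowest bank period the post-due latency is approximately constant
(about 190 ms), so measured from the train offset it grows with slope
about one in SOA; the across-trial standard deviation stays under 10--20
ms.  Beyond 200 ms SOA no sustained representation forms, the
free-running detector's phase at the due time depends on the train
length, and latencies scatter by hundreds of milliseconds.
`osr_boundary()` reports the largest grid SOA below which the spread
stays within 20 ms; with the default bank this is 200 ms, set by the
slowest bank resonance.  A prolonged CONST control produces a plain
offset response.

**Sequence MMN** (`example4_mmn()`): three nodes; node 1 carries the
RAND envelope, node 2 the REG envelope (identical amplitude and ramps,
so every asymmetry is connectional), node 3 the detector.  The REG-to-C
coupling is drawn from the scan's Inc-Off family (activity raised during
REG -- the higher REG-block RMS -- plus an offset transient when REG
ends), the RAND-to-C coupling from an On-type family without an offset
transient.  A REG-to-RAND switch therefore produces a transient (REG
offset response), while RAND-to-REG produces none; sequence onset and
offset produce transients through the RAND-side coupling.  Direct R-R
weights are exposed (`w_12`, `w_21`) but default to zero, as the
one-way transition asymmetry already emerges from the detector-side
couplings.  Readouts are prominences of the post-transition RMS peak
over the flanking plateaus.

## What the synthetic protocols do and do not capture

All inputs are clean rate envelopes: trapezoidal steps (amplitude 1.5
spikes/s, 10 ms linear ramps -- ramp shape is a package choice), periodic
trains (omission = truncation plus a recorded due time), and REG/RAND
block envelopes.  There is no acoustic front end, no stochastic
background, no conduction delays, and the "sequences" of the MMN example
are represented only by which regularity node is driven -- not by actual
tone patterns.  Passing tests therefore demonstrate properties of the
network mechanism (disinhibition-based edge detection, resonance-based
temporal expectation, connection-asymmetry-based one-way transition
responses), not quantitative fits to recorded MEG.

## Numerical choices and degenerate inputs

RK4 at `dt` 0.5 ms; settle 2 s (2.5 s for the bank, whose slow detector
needs longer); zero-state initialization throughout, so any bistability
is resolved the same way every run.  Scan failures (non-finite states)
are counted and labeled `others`.  Covariance windows are all-zero until
filled.  Peak detection returns a found-flag rather than erroring on
monotone signals; window maxima are taken strictly inside windows.  The
2-D embedding of solution sets is deterministic PCA (classical MDS as an
alternative); it is cosmetic plumbing, and no claim depends on its
coordinates.  Routine problem sizes: 4000-point scan subsample, 8 trials
per SOA, 11-SOA boundary grid -- chosen so the whole suite runs in a few
minutes while keeping sampling error well inside every stated band.
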