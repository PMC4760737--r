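---
title: "An agent-based model of a two-species gut community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of a two-species gut community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gutabm simulates two bacterial species competing and cross-feeding in a
two-dimensional section of gut. It is an individual-based model: every
bacterium and every parcel of metabolite is an agent. The package exists to
study emergent community phenomena — stabilization by feedback loops,
bistability, spatial segregation, recovery from antibiotic perturbation,
and the spread of antibiotic resistance under a fitness cost — none of
which are programmed in directly.

```{r setup}
library(gutabm)
```

## The model

**Agents.** Bacteria of type 1 and type 2 are active agents with a position,
an energy store, a hunger clock, toxin and drug loads, and a resistance
flag. Passive agents are substance parcels ("quanta", 1 mmol each by
default): dietary polysaccharide (PS), host polysaccharide (PS-gut),
the short-chain fatty acids (SCFAs) acetate, propionate and butyrate,
two toxins, and antibiotic.

**Metabolism.** The reaction scheme is Michaelis–Menten throughout: a
conversion with rate constant $k$ proceeds at $100\,k\,[S]/(K_m+[S])$
mmol/h. Type 1 ferments PS and PS-gut to acetate
($k = 0.16$); type 2 ferments PS to acetate ($0.16$) and propionate
($0.26$). The acetate-to-butyrate conversion ($0.31$) belongs to the
configured `acetate_consumer_type`, by default type 2 — the exploitation
link in which the dominant species consumes its partner's fermentation
product. (The published constant table formally lists the acetate
conversion under type 1, but every functional description of the
network — type 2 holding "more energy sources", the toxin–antitoxin
pseudocode keying on type 2 acquiring acetate, and the rationale for
feeding type 1 from the gut — requires the dominant type 2 to be the
acetate consumer. We verified the alternative: with type 1 as acetate
consumer the basic model acquires a stable coexistence attractor through
type 1's exclusive cross-fed niche, and none of the published stability
or perturbation phenomenology can be reproduced. The literal wiring
remains available via `acetate_consumer_type = 1`.)

Each consumed quantum converts 1:1 into a product quantum emitted at the
bacterium's position, adds 1 quantum to the bacterium's energy store, and
resets its hunger clock. Consumption per tick is a Poisson draw with mean
$\text{rate} \cdot dt / \text{quantum}$, capped by the particles actually
within the 100 µm contact radius; the substrate concentration entering the
rate law is read from a coarse 20 × 10 concentration grid (one quantum in a
cell contributes `conc_per_quantum` mM, default 1).

**Behavior cycle.** Per tick a bacterium: dies if its hunger clock exceeds
its starvation limit (drawn once per life from $U(0, n\cdot
\text{EatPeriod}]$, $n = 3$ by default); divides if its energy reaches the
division threshold (4 mmol by default); otherwise converts substrate in
contact range, moves at 7000 µm/h toward the nearest edible particle
within the 3500 µm search radius, or takes a random-walk step. Daughters
split at the parent position with energy zero and freshly drawn starvation
limits. Update order is re-randomized every tick.

**Transport.** Passive particles are advected along the gut with the
wall-adherent profile $v(y) = k_{gut\_out} \cdot L \cdot (1 - |y - D/2|
\cdot 2/D)^2$: maximal on the centerline, zero at the walls where material
clings to mucus. Lateral motion is a reflected uniform jitter
(±50 µm/tick). Particles crossing the outlet are excreted. SCFA parcels in
the wall zones are absorbed through saturable competitive MCT transport,
$V = k_{trans} (C_s/K_s) / (1 + \sum_j C_j/K_j)$ with $k_{trans} = 8.3$
mmol/h and $K_m$ 15.0 mM (acetate, propionate) and 21.3 mM (butyrate); per
tick each wall-zone parcel is absorbed with probability $\min(1, V\,dt /
\text{local pool mass})$, which reproduces the continuum rate in
expectation. The summed flux is analytically bounded by $k_{trans}$, well
inside the published absorption ceiling of 33.2 mM/h.

**Feedbacks.** Seven optional mechanisms couple the species and the gut:

* **FB1** (toxin–antitoxin): each acetate quantum converted by the
  producer type becomes, with probability `fb1_toxin_percentage` (50% at
  the calibrated default), a toxin lethal to the producer's own type and
  digestible by the partner, instead of butyrate.
* **FB2**: when the configured source type is outnumbered by more than a
  threshold, it co-emits toxin against the other type alongside its normal
  products.
* **FB3**: the gut emits toxin against type 2 while
  $N_2 - N_1 >$ threshold.
* **FB4**: the SCFA-sensed analog of FB3 — the gut emits the same toxin
  while the sensed SCFA difference exceeds a threshold. The default senses
  propionate − butyrate (the dominant type's signal against the
  partner's); the printed literal orientation butyrate − propionate is
  available via `fb4_difference = "but-pro"` but never fires under the
  model's flows, where propionate always exceeds butyrate.
* **FB5 / FB6**: the gut emits toxin against type 1 while butyrate exceeds
  a threshold, and against type 2 while propionate does. These directions
  are fixed by the published interaction signs (FB5 harms type 1 and
  destabilizes; FB6 helps type 1 at type 2's expense and stabilizes).
* **FB7**: the gut produces host polysaccharide — digestible only by
  type 1 — while butyrate is below a threshold (calibrated to 2500 quanta
  so the subsidy is withdrawn only when butyrate is plentiful), at
  `fb7_ps_rate` quanta per triggered tick (0.3, i.e. 15 mmol/h at the
  desk-scale tick).

Bacterial toxins (FB1, FB2) disperse uniformly within
`toxin_dispersal_radius` (2000 µm) of the producer before acting. This is
load-bearing: emitted at the producer's exact position, a self-lethal
toxin is reabsorbed by its producer within a tick, which reduces FB1 to a
density-independent death tax and destroys the mutualistic coupling. With
dispersal, the partner's scavenging (it *seeks* the toxin as food within
its search radius) makes the producer's death rate fall with partner
density — the negative feedback that actually stabilizes the pair.
Gut-emitted particles appear in thin bands along the walls. Toxins decay
spontaneously at `k_antitoxin1/2` (0.05 1/h).

**Antibiotics and resistance.** Drug enters near the inlet in the lumen
during gavage windows (dose rate × duration, 1 or 3 gavages/day over a
course, or continuously). Parcels are advected like any particle — most
drug travels the lumen, so the wall zones are a partial refuge. A
bacterium absorbs drug quanta on contact and dies when its accumulated
load reaches its lethal threshold (0–4 quanta; `Inf` encodes a fully
resistant type), releasing the load back into the gut. At division each
sensitive daughter mutates to resistant with probability $p =
\min(1, \alpha C / R_c)$, where $C$ is the local drug level (contact
quanta plus carried load) — the simplest form that is linear in exposure
and damped by the fitness cost. Resistant bacteria convert nutrients at
rates divided by the retardation constant $R_c \ge 1$ for life; resistance
is inherited and never reverts.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k_intake` | 40 | mmol/h | dietary PS supply; sets the community's carrying capacity |
| `eat_period` | 8 | h | meal spacing; 320 PS quanta arrive per meal |
| `k_gut_out` | 0.02 | 1/h | clearance; centerline residence time is $1/k$ = 50 h |
| `division_threshold` | 4 | mmol | energy per division; the main fecundity knob |
| `eat_range_multiplier_n` | 3 | — | starvation limits are $U(0, 24]$ h |
| `fb1_toxin_percentage` | 50 | % | strength of the toxin–antitoxin coupling |
| `retardation_constant_Rc` | 1 | — | fitness cost of resistance |
| `mutation_rate_scale_alpha` | 0 | 1/quanta | mutation pressure per unit local drug |

The published table leaves several quantities open; they are fixed here
once, as follows. Tick length 0.01 h (a 70 µm movement step, well inside
the search radius). One quantum = 1 mmol (the simplest bridge between the
table's agent counts and mmol/h rates; the division threshold is stated in
mmol so that refining the quantum leaves mean dynamics unchanged). Contact
radius 100 µm, distinct from the 3500 µm *search* radius. Division
threshold 4 mmol — with the published rate constants this gives type 2 the
higher division rate, as asserted. Conversion-reaction Michaelis constants
default to the transport values (15.0 / 15.0 / 21.3 mM), the only
concentrations of the right scale available. The clearance constant
follows the published table (0.02 1/h) rather than the 0.08 1/h quoted
from transit-time physiology; both are one config key apart.

## The desk-scale profile

`desk_params()` scales the geometry to a 150 000 × 30 000 µm section at a
0.02 h tick with all kinetics and initial counts untouched (800 bacteria).
In the full-size gut the two species barely meet and every contest is
decided by slow drift; at desk scale the same rules produce decisive
competition in runs of 25 000–50 000 ticks (500–1000 h), seconds to a
couple of minutes each on one core. All screens below use this profile;
the geometry, like everything else, is one config key away from the
published dimensions.

With it, the single-feedback stability screen reproduces the published
classification: the basic network and FB2 and FB5 lose type 1 (long-run
mean below the coexistence floor of 10 bacteria), while FB1, FB3, FB4, FB6
and FB7 sustain both types across seeds. The screen's run length (35 000
ticks = 700 h) is the time the basic model needs to finish excluding
type 1; the stabilized networks equilibrate much earlier. The other
standing experiments use the same profile: initial-condition sweeps run
20 000 ticks per cell, antibiotic-course experiments equilibrate for
300 h before a 3-day course and continue to 760 h, and the
resilience-by-feedback-count comparison uses a continuous once-daily
course at 100 mmol/h over a 400 h horizon.

## Analysis layer

Observables are computed from trajectories (per-tick counts and cumulative
birth/death/mass ledgers) and snapshots (agent tables):

* **Segregation index**: for each bacterium the same-type fraction among
  neighbors within $r = 30\,000$ µm, averaged per type over the five gut
  zones (wall mucin fifths, lumen, and the border bands, which
  intentionally overlap the mucin/lumen split as published). Bacteria with
  no neighbor in range are excluded. The production path uses grid-bucket
  neighbor search and is tested for exact agreement with an all-pairs
  oracle.
* **Recovery time**: hours after a course's end until both types regain
  80% of their pre-course baseline (mean over the 100 h before the course).
* **Resilience time**: under continuous treatment, hours until either
  type falls to 100 bacteria.
* **Outcome classes**: from the resistant fraction $R/(R+S)$ averaged over
  a post-course window — class 1 above 0.7 (the published dominance
  level), class 3 below 0.1 with no resistant survivors, class 2
  otherwise. The 0.1 floor and the window length (10 × course length) are
  package conventions.
* **Bistability**: long-run mean $(N_1, N_2)$ of each sweep run (final
  third of the trajectory), kernel-smoothed (`MASS::kde2d`, normal
  reference bandwidth floored at 5% of the data range); modes are local
  maxima above 15% of the global density maximum that are topographically
  separate — a candidate connected to higher density without descending
  below half of its own height is a shoulder or sampling ripple, not a mode. Both guards
  suppress sampling ripples at the reduced sweep sizes used in testing.

## What the synthetic fixtures do and do not show

`make_snapshot()` and `make_trajectory()` generate deterministic agent
tables (layered, checkerboard, mixed, clustered) and piecewise count
series with crossings at known times. They exercise every observable
definition — a segregation index of exactly 0.5 on a checkerboard, a
recovery time of exactly 37 h — without running the simulator, so tests of
the analysis layer are sharp and fast. They emulate geometry, not ecology:
a passing fixture test validates the *definition*, while claims about the
model's behavior (stability, bistability, resistance outcomes) rest on the
simulation screens, and claims about real guts rest on neither.

## Numerical and degenerate-input choices

Randomness comes from R's single RNG stream; a run is byte-reproducible
from its seed, including agent shuffling. Poisson consumption draws are
capped by locally available particles, so mass ledgers balance to exact
quanta at every tick (this is asserted in tests, including under
treatment). Empty worlds, empty zones, isolated bacteria (no neighbor in
range) and extinct communities all return explicit markers (`NA`) rather
than propagating division by zero. Censoring (recovery or critical
thresholds never reached) is reported as `NA`, never as a large number.
Reflecting boundaries assume steps smaller than the domain — true for all
supported parameterizations.

## Known limitations

The gut is a 2-D rectangle: no peristalsis, pH, oxygen, or mucus
viscosity. Stoichiometry is 1:1 per conversion and there is no
intracellular state beyond the energy counter. Bacteria are not advected
by the flow (the published population accounting admits only division and
the three death causes, so flow washout of bacteria is excluded by
construction); their wall affinity emerges from where food and refuge are,
not from adhesion mechanics. The resistance model does not distinguish
mutation from horizontal transfer and has no back-mutation. Feedback
constants beyond those printed were never published; the values here are
calibrated once against the published stability classification and kept
fixed everywhere else.

One reported phenomenon resists this implementation: a bistable
mixed-versus-layered regime under FB1 + FB7. Here that network converges
to a single attractor across initial counts (200–3000 per type), seeds,
toxin percentages, dispersal radii, subsidy rates and trigger thresholds.
Two structural facts block it: the butyrate pool — FB7's sensor — is
supply-limited (any surviving type-2 population converts essentially all
available acetate), so it cannot distinguish community states; and with
hundreds of independently deciding agents, niche occupancy self-averages,
so no collective spatial configuration can lock in. A bistable regime
would need a community-state-sensitive global signal or an agent-level
positive feedback (adhesion, quorum behavior) that the model's reaction
network does not contain. The sweep driver and mode counting are fully
implemented and report whatever the dynamics produce.
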