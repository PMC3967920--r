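---
title: "The crypt-villus model: mechanisms, calibration and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The crypt-villus model: mechanisms, calibration and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cryptvillus is a discrete-time, spatially explicit agent-based model of the
ileal crypt-villus epithelium. This vignette documents the model itself:
what is simulated and how, which parameters matter and why they have the
values they do, the design choices made where the design was genuinely
open, and what the simulator can and cannot say about real tissue.

## Tissue representation

Crypts and villi are fixed rectangular prisms whose epithelial surfaces are
"unwrapped" onto 2-D lattices with circumferential wrap-around: by default
one crypt (16 x 18 patches) joined rim-to-base to one villus (16 x 75
patches), with a patch edge of 20 um — one cell diameter, so a patch holds
at most one live cell (necrotic debris may be co-occupied). The lattice is
deliberately taller than the homeostatic tissue: the *position* of the
crypt-villus junction and of the villus tip are emergent, read off from
where undifferentiated and differentiated cells actually sit, which is what
lets perturbations deepen the crypt or shorten the villus. An abstracted
blood vessel sits at mid-crypt depth and is the arrival point for
circulating inflammatory cells.

The engine simulates one crypt-villus complex; the geometry module builds
and validates general `n_villi x crypts_per_villus` topologies (adjacency,
rim-base links), which is where a multi-complex engine would start.

## Time scales

Cells act physically every `dt_cell = 15` min (about 10^3 s, the natural
scale of migration and division). Within a tick, signaling is assumed to
have run to its short-time outcome: each intracellular pathway is advanced
by an exact exponential relaxation towards an environment-determined
target, and the genuinely delayed switches carry explicit timers. A
generic time-delayed-rule engine (`delayed_rule()`, `step_rules()`)
provides the per-cell semantics; its discretization converges to the
corresponding delayed ODE as `dt -> 0`, which the test suite checks
against the analytic exponential. Delays inside the engine are quantized
to the 15-min tick; every delay in the model is of that order or longer,
so nothing is lost relative to a finer signaling sub-step, and the
exponential updates are exact integrators rather than Euler steps.

## Morphogen fields

Extracellular species live on the lattice with explicit 4-neighbor
diffusion, first-order decay and point sources; boundaries are closed at
the crypt base and villus tip and wrap circumferentially. The per-tick
operator is precomputed as a sparse matrix (the substepped explicit kernel
with far tails truncated and row mass renormalized, so conservation is
preserved and entries stay non-negative). Units are arbitrary; every
threshold is expressed relative to the configured source strengths.

* **Wnt** is emitted by the bottom two crypt rows and decays upward
  (decay length ~5.5 patches). Cells with local Wnt above `wnt_eps`
  accumulate beta-catenin (saturating at 1); when Wnt is lost, the
  destruction complex activates after a 30-min delay and beta-catenin
  decays with a 2-h time constant. Proliferation requires beta-catenin
  >= 0.5; differentiation fires when it falls below 0.3. The travel time
  across this window is what creates the band of undifferentiated,
  Wnt-free cells just below the junction.
* **SFRP1** is secreted by enterocytes in proportion to the Hedgehog
  signal they receive and annihilates Wnt stoichiometrically on contact.
  The Wnt/SFRP1 annihilation front, not a hard-coded height, sets the
  crypt depth: with SFRP1 gone (Hedgehog inhibition, villus loss) Wnt
  runs out to its decay-limited extent and the crypt deepens.
* **Free BMP** is held spatially uniform (isotropic), as observed; the
  *activity* gradient comes from receptor availability, below.
* **TLR4 ligand (DAMPs)** is emitted by necrotic debris until clearance;
  the inflammatory cytokines (TNF-a, IFN-g, IL-6, IL-10, IL-13, IL-15)
  are secreted by inflammatory cells. IL-13/IL-15 are tracked for network
  completeness but drive no behavior.

## The intracellular network

All live cells carry the same network. The morphogenic half: Wnt /
beta-catenin (proliferation and differentiation timing); BMP receptor
binding, where receptor availability ramps with time since
differentiation — a cell-intrinsic maturation clock, chosen as the
mechanism behind the junction-to-tip BMP activity gradient because the
observed gradient (uniform ligand, graded binding) does not identify a
mechanism; and mutually inhibitory PTEN and Hedgehog with
`akt = 2/(1 + pten)` as the survival readout. The apoptosis hazard of an
enterocyte is a steep sigmoid in the drive

    bound_BMP * (w_akt * (akt0/akt)^beta + w_hh * hh_signal) / (w_akt + w_hh)

with NF-kB as a multiplicative suppressor bounded below at 0.1x. Because
PTEN loss raises Hedgehog (and vice versa) and the two arms enter the
drive symmetrically, inhibiting either one alone leaves the long-run
drive near 1 — the redundancy that makes single-pathway knockouts
architecture-neutral — while chronic TLR4 tone raises PTEN *and* lowers
Hedgehog, pushing the drive up and shortening the villus. The Hedgehog
signal used by the PTEN axis and the hazard is the tissue mean of the
extracellular field normalized to its homeostatic value: a hormone-like
readout of villus mass, which avoids edge artifacts of the thinly
populated tip rows. The exponent `beta = 2.6` is set so that the flux
increase of a deepened crypt under Hedgehog blockade is compensated and
the villus returns to near its normal height.

The inflammatory half: TLR4 activation saturates in local ligand
(`K = 8`); a slow filter of activation (`tau = 12 h`) is the chronic tone
feeding PTEN, so acute insults barely move PTEN but sustained stimulation
remodels the tissue. RIP integrates membrane damage with slow (12-h)
resolution from two sources: contact with adjacent debris, scaled by
ischemic sensitization, and ambient DAMP exposure above an activation
floor — a small ungated component plus a strong component proportional to
sensitization, so a DAMP storm is lethal to ischemia-primed tissue and
nearly harmless to healthy tissue. Necrosis fires when RIP crosses 1
(stems: 10x, niche protection). One global hazard exception exists: when
no live cell retains active Wnt signaling the proliferative compartment is
extinct, trophic support is assumed lost, and enterocyte apoptosis gets a
floor — this engages only in the total-Wnt-loss endgame and produces the
observed organ-failure timeline.

## Cell mechanics and calibration targets

Transport is division-driven column displacement (a daughter pushes the
contiguous stack above it one row tipward; at the lattice top the last
cell is shed) plus a gap-filling upward drift. Stem cells (bottom two
crypt rows) divide asymmetrically — the daughter is inserted above the
whole niche — and never migrate. The realized column flux is therefore
the birth rate per column, ~0.24 rows per tick at homeostasis.

The calibration targets are the classical ileal numbers: crypt depth ~1/4
of a ~1 mm villus and complete epithelial renewal in ~5 days. These pin
the free rates as follows: villus height = flux x enterocyte death age,
and renewal = crypt residence + death age. Division probabilities
(`p_stem = 0.003`, `p_div = 0.025` per tick) set the flux and a slow crypt
residence (~2.3 days, dominated by the stem-driven bottom rows); the
maturation ramp (`bmp_ramp_min = 5250` with threshold 0.8) sets a ~2-day
enterocyte lifespan. Together: ~50 villus rows (= 1 mm), renewal ~4.4
days, and — because the lifespan is ~2 days — total Wnt loss leaves the
villus extinct within ~2 days of Wnt elimination, consistent with the
reported organ-failure timeline. A stated ~10^4-s cell survival figure is
inconsistent with 5-day whole-epithelium renewal; the model is calibrated
to the renewal target.

## Ischemia/reperfusion

During ischemia, division and migration are suspended and every live cell
accrues I-FABP linearly in time and an injury dose that accelerates
(quadratic in time), both scaled by an axial severity gradient (floor 0.36
at the crypt base, 1 at the tip — the tip is most ischemic, but deep
tissue is not spared at long durations). At reperfusion:

* Enterocytes above a severity threshold that falls with the log of the
  ischemic duration are *sloughed*: shed cleanly into the lumen, no
  debris, no DAMPs. 30 min sheds roughly the top quarter; hours-long
  ischemia sheds most of the villus. With sloughing disabled those same
  impending-necrotic cells die in place as DAMP-emitting debris.
* Stem and TA cells die by dose: clean (apoptotic) above ~140 dose units,
  necrotic in place above ~200. Stems have a shallower curve, so
  intermediate ischemia (5 h) kills part of the stem pool — the
  recoverability-limiting event — while 6 h kills the compartment
  outright.
* I-FABP persists (daughters inherit it), and it *sensitizes* RIP: the
  quadratic sensitization multiplier makes retained debris plus primed
  tissue self-amplifying. This is what separates the two no-sloughing
  outcomes: at 30 min the DAMP storm chews deep into the sensitized villus
  (persistent alteration), at 3 h it overwhelms the crypt before clearance
  can win (death). With sloughing the same histories shed the primed cells
  into the lumen first — the protective effect.

Outcomes are classified on the final 24 h of a 72-h post-reperfusion
window: DEAD if the live population ever reaches zero; RECOVERED if the
window means of both compartments are within +-10% of baseline with no
debris left; otherwise PERSISTENT_ALTERATION. Window means (not per-tick
values) are compared because the discrete junction row makes instantaneous
compartment counts jump by a whole circumference; the +-10% band sits
above seed-to-seed noise measured at baseline. The 72-h window gives
full-villus regrowth (~2.5 days at the hyperplastic flux) room to
complete while still catching the delayed rebuild of storm-damaged
crypts.

## Inflammation

Neutrophils and macrophages arrive at the vessel with probability
saturating (Hill coefficient 1) in local DAMP + TNF-a — bounded influx
during long insults — and resident inactive monocytes (1 per 50 patches)
activate to macrophages where IFN-g from debris-engaged neutrophils
exceeds threshold. Chemotaxis is noisy gradient ascent (3 lattice steps
per tick, 35% exploratory steps): pure greedy ascent piles every agent at
the plume maximum and leaves off-gradient debris uncleared, while the
noisy walk spreads the swarm and finds stragglers; a slow autolysis
(0.5%/tick) guarantees isolated remnants resolve. Phagocytosis clears one
debris unit per engaged cell per tick. A villus-wide wound (~780 debris)
clears in 15-18 h, within the day-scale window reported for mucosal
wounds, and the crypt growth spike that precedes villus reconstitution
emerges from SFRP1 loss alone.

## Chronic stimulation and metaplasia

Continuous low-grade TLR4 exposure (default level 8, i.e. half-saturating
activation — the lowest level in the calibration sweep that produces a
stable shifted equilibrium) raises the chronic tone, which raises PTEN,
lowers Akt and internal Hedgehog, and therefore both *shortens the villus*
(drive up) and *deepens the crypt* (SFRP1 down). The result is a stable,
non-inflamed equilibrium with the colonic ratio shift; levels above the
RIP activation floor (tlr4 > 0.6, reached near level ~100) instead tip the
tissue into necrosis, giving a clean threshold separation between
metaplasia and injury.

## Numerical choices and degenerate inputs

Diffusion substeps obey `4 D dt_sub <= 0.8` (entries non-negative; a
user-supplied unstable substep is a configuration error, not a silent
negative concentration). Annihilation takes the pointwise minimum of Wnt
and SFRP1, so neither can go negative. All stochastic decisions draw from
one seeded stream in a fixed phase order (division order is shuffled
within its phase); a fixed seed and config reproduce a run byte for byte.
Physical actions are evaluated in vectorized phases
(differentiate/necrose/apoptose/divide/migrate) rather than a per-agent
shuffle of interleaved actions; only the division order is randomized,
which is the one place order matters (column pushes). Empty tissues,
zero-duration runs and zero-strength scenarios are exact no-ops;
checkpoints round-trip bit-exactly through a plain-text format.

## What the simulator does and does not show

Everything here is calibrated against a synthetic, self-generated
baseline; no external data enter the model. Passing the validation suite
shows that one coherent parameterization reproduces the qualitative
orderings and the handful of quantitative anchors (1/4 ratio, 1 mm villus,
5-day renewal, day-scale wound clearance) simultaneously — not that the
mechanisms are uniquely identified. Known limitations: no Paneth, goblet
or enteroendocrine lineages (the goblet-cell shift of metaplasia is out of
scope); no crypt fission, so the deepened-crypt states understate real
hyperplastic behavior; EphB/Ephrin is a readout only, so no cell sorting;
no 3-D lamina-propria diffusion or mechanics; a single crypt-villus
complex, so wound healing cannot recruit neighboring villi; and the
BMP-activity maturation clock is one admissible mechanism for the
junction-to-tip gradient, not an established one.

## Problem sizes used by the test and acceptance runs

Validation uses the default single 16-wide complex (1,488 patches, ~960
cells at homeostasis): 14-day baselines over five seeds, 4-day scenario
runs (five seeds for the pathway inhibitions, wound and metaplasia), the
eight-case ischemia sweep over three seeds with a 96-h follow-up, and
five-seed measurements of the four reported quantities. These sizes give
seed-level reproducibility of every qualitative claim while keeping a full
validation pass in the minutes range on one core.
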