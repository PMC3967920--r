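# cryptvillus

An agent-based simulator of the ileal crypt-villus epithelium, built to
study how inflammation acts as a controller on the morphogen signaling
that maintains intestinal tissue architecture.

## The scientific problem

The small-intestinal mucosa is a conveyor belt: Wnt-driven stem and
transit-amplifying (TA) cells proliferate in the crypt, daughters migrate
up, differentiate into enterocytes at the crypt-villus junction, and are
lost near the villus tip, renewing the whole epithelium about every five
days while keeping the crypt roughly one quarter the height of a ~1 mm
villus. This architecture is not fixed anatomy but a dynamic equilibrium
of morphogen gradients — and inflammation perturbs exactly those
gradients. Clinically important phenotypes (mucosal wounds,
ischemia/reperfusion injury, and the colonic metaplasia of chronically
inflamed ileal pouches) are all architectural outcomes of the same
cell-and-signal machinery.

`cryptvillus` represents crypts and villi as rectangular prisms unwrapped
onto 2-D lattices. On the lattice:

* Morphogen and cytokine fields (Wnt, SFRP1, Hedgehog, free BMP, TLR4
  ligand/DAMPs, TNF-α, IFN-γ, interleukins) diffuse and decay:
  `c_{t+dt} = A c_t + s·dt`, with a precomputed sparse lattice-diffusion
  operator `A`.
* Gut epithelial cell agents carry an intracellular network evaluated as
  time-delayed rules: Wnt/β-catenin (destruction-complex switching),
  BMP receptor binding that ramps with time since differentiation,
  mutually inhibitory PTEN ⊣ Hh with `Akt = min(akt_max, 2/(1+PTEN))`, and
  a TLR4 → NF-κB / RIP inflammatory arm. The enterocyte apoptosis hazard
  is a steep sigmoid in

  `drive = boundBMP · (w_a (Akt₀/Akt)^β + w_h Hh_signal) / (w_a + w_h)`,

  so PTEN and Hh redundantly control villus maintenance, and chronic
  TLR4 tone (which raises PTEN and lowers Hh) shortens the villus while
  its SFRP1 side-effect deepens the crypt — the metaplasia crosstalk.
* Inflammatory agents (resident monocytes, recruited neutrophils and
  macrophages) arrive at an abstracted vessel, chemotax noisily along
  IFN-γ/DAMP gradients and phagocytose necrotic debris.

Crypt depth, villus height and the junction position are *emergent*: the
Wnt/SFRP1 annihilation front sets the proliferative compartment and the
maturation-clock death age times the division flux sets the villus.
Seven scenario families reproduce the canonical experiments: baseline
homeostasis, Wnt / Hedgehog / PTEN inhibition, a villus-wide necrotic
wound, ischemia/reperfusion (30 min – 6 h, with or without I-FABP-mediated
enterocyte sloughing) and chronic low-grade TLR4 stimulation.

## Worked example

```r
library(cryptvillus)

run <- simulate_tissue(days = 10, seed = 1)
run
#> <cv_run> 960 ticks (10 days), scenario: baseline
#>   final: crypt 192, villus 824, necrotic 0, ratio 0.226

glance(run)[, c("crypt_mean", "villus_mean", "ratio_mean",
                "villus_height_mean_um")]
#>   crypt_mean villus_mean ratio_mean villus_height_mean_um
#> 1      203.7         799     0.2482                  1028

measure_renewal(run$state, max_days = 9, seed = 101)
#> [1] 4.45
```

The final-day averages say the tissue has settled at ~204 crypt cells
below the junction and ~799 enterocytes above it, a crypt:villus ratio of
0.25 and a villus of ~1.03 mm — the homeostatic ileal architecture — and
a labeled cohort of cells is ≥99% replaced in ~4.5 days. Perturbations
start from such a state:

```r
chk <- run$state                          # homeostatic checkpoint
w   <- run$metrics$time_min > 9 * 1440
bs  <- list(crypt_mean = mean(run$metrics$crypt_alive[w]),
            villus_mean = mean(run$metrics$villus_alive[w]))

ir <- run_ischemia_reperfusion(chk, ischemia_minutes = 30,
                               sloughing_enabled = TRUE, seed = 7)
classify_outcome(ir, bs)
#> [1] "RECOVERED"
```

With sloughing disabled the same 30-minute ischemia leaves a persistent
alteration, and 3 h of ischemia without sloughing kills the tissue —
the protective role of enterocyte shedding. `autoplot(run)`,
`plot_state(run$state)` and `plot_gradient(gradient_profile(...))` give
the standard population-curve, tissue-snapshot and axial-profile views;
`tidy(run)` returns the per-tick time series as a tibble. A thin
command-line front end lives at `inst/cli/cryptvillus`
(`run`, `sweep-ischemia`, `validate-config`).

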