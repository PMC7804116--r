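---
title: "Thermodynamic modelling of inducible promoter MPRA libraries"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promotherm)
```

This vignette is the package's account of the science it implements: the
occupancy model and its assumptions, the coordinate and energy conventions,
what the synthetic-data generator does and does not emulate, the numerical
choices in the fitting engine, and the design decisions taken where the
design was genuinely open.

## The model

An IPTG-inducible promoter is modelled as a set of binding sites: a core
RNAP site (the σ70 −35/−10 element pair), a proximal LacI operator
downstream of the transcription start site, and one or two operators far
upstream (the distal and, in the three-operator architecture, "distal+"
sites). The promoter's occupancy state space is every combination of

* RNAP bound or free,
* LacI bound or free at each operator,
* at most one DNA **repression loop**, in which LacI bound at the proximal
  site tethers one bound upstream site; the loop occludes RNAP, so looped
  states never have RNAP bound.

For the two-operator architecture this gives 9 states (all 8 binding
combinations plus the single looped state); for the three-operator
architecture, 20 (16 binding combinations plus 4 looped states: loop to the
distal site with distal+ free or bound, and loop to distal+ with distal
free or bound). `enumerate_states()` lists them and the test suite checks
the counts against a brute-force filter over all raw occupancy tuples.

Each state's statistical weight is the Boltzmann factor `exp(-E)`, where
`E` sums the binding free energies of the bound elements, the looping free
energy for looped states and, in the presence of IPTG, a penalty
`delta_iptg` per bound LacI unit. All energies are expressed in units of
thermal energy kT with the inverse temperature absorbed, and **lower energy
means stronger binding**; `+Inf` encodes a site that cannot bind (a
scrambled operator) and contributes weight exactly zero, avoiding any
overflow handling.

States with RNAP bound and the proximal operator *free* transcribe at rate
`r_max`; every other state contributes the background rate `r_min`:

$$
\mathrm{expression} \;=\; \frac{r_\min Z + (r_\max - r_\min) Z_\mathrm{active}}{Z},
\qquad Z = \sum_s e^{-E_s},\quad
Z_\mathrm{active} = \sum_{s:\,R=1,\,P=0} e^{-E_s}.
$$

Expression therefore always lies in `[r_min, r_max]`, is non-decreasing in
the operator energies (weaker repression ⇒ more expression) and
non-increasing in the core energy. Fold change — induced over uninduced
expression — is ≥ 1 whenever `delta_iptg ≥ 0` and exactly 1 when it is 0.

Model assumptions worth stating explicitly:

* **RNAP and proximal LacI may co-occupy.** The expression rule only
  requires the proximal site to be free for the state to be *active*; the
  co-occupied state exists and contributes `r_min`. The alternative
  (strict exclusion) would remove two states from the space; the expression
  rule itself implies the co-occupied states exist.
* **The IPTG term is an additive energy penalty per bound repressor**
  (equivalently, a multiplicative weight scale per bound LacI unit). It is
  isolated in one place (`state_weight()` and the closed-form partition
  functions), so an alternative form is a one-line change.
* **Distal+ sites reuse the distal-position energy of the same operator
  sequence.** This is what makes zero-shot prediction of the three-operator
  library possible from a two-operator fit.
* **At most one loop at a time, and loops exclude RNAP.** Simultaneous
  double loops are sterically implausible and would add parameters nothing
  in the data constrains.
* Out of model scope: CAP activation, supercoiling, kinetic (non-
  equilibrium) regimes, and explicit repressor copy-number bookkeeping —
  effective binding energies absorb the latter.

## Coordinates and library designs

Positions are genomic-style relative to the transcription start site:
TSS = +1, there is **no position 0**, and operator intervals are inclusive
spans on the sense strand. "Centred at k" is exact for odd-length parts
(a 21-mer centred at +11 spans +1..+21; a 23-mer centred at +12 spans
+1..+23); for even lengths the declared centre is the middle position
nearer the TSS. Parts are placed onto a lacUV5-like backbone shipped in the
part catalog (a synthetic stand-in sequence — every enumeration count and
placement rule is independent of the actual letters).

The five architectures and their design sizes:

| library | factors | size |
|---|---|---|
| spacing | 6 TFs × (34 distal centres −83..−116 × {intact, proximal scrambled, distal scrambled} + proximal-only + both-scrambled) | 624 |
| pcombo | 10 proximal × 4 −35 × 4 −10 × 10 distal | 1600 |
| pmultiple | 5 distal+ × 5 distal × 4 −35 × 4 −10 × 5 proximal | 2000 |
| pspacer | 5 distal × 4 −35 × 4 −10 × 5 spacer × 11 interoperator distances (46–56 bp) | 4400 |
| psteric | 4 −10 × 5 core × 5 proximal × 4 UP × {ext −10, none} × {+11, +30} | 1600 |

Two conventions deserve a note. First, the spacer-region operators are the
21 bp LacI sites trimmed by 2 bp at each end so that the 17 bp site exactly
fills the −29..−13 spacer between the hexamers. Second, the `pspacer`
interoperator distance `d` is the design variable and the distal operator
centre is placed at −(20 + d); this puts the gap between the distal site's
downstream edge and the −35 element at `d − 26` (20–30 bp across the
design), which is the spacing the architecture is defined by. For
`psteric`, the 21 bp core operator centred at −26 *replaces* the −35
element (that architecture has no −35 slot), and a proximal site at +30 is
56 bp centre-to-centre from the core operator — a spacing favourable for
loop formation.

The spacing-library decomposition (34 × 3 + 2 controls per TF) is a design
decision: the three series are the intact pair and the two single-site
scrambles, and the two position-independent controls are a proximal-only
variant (no distal cassette) and a both-scrambled variant placed at the
−90 reference position. Scrambled sites preserve length and base
composition (`scramble_operator()` is a seeded permutation).

The shipped part catalog uses the native lac operators O\_1, O\_2 (as a
3-mutation variant) and O\_3, half-site palindromes constructed from them
(including the symmetrised O\_sym), a seeded scramble of O\_1 as the
non-binding negative control, and synthetic stand-ins for the six
transcription-factor spacing sites and the UP elements. Catalog rows are
unique per (name, role) — the same operator legitimately appears in both
the proximal and distal role.

## Count processing

The pipeline follows the standard MPRA recipe, in order:

1. `normalize_counts()`: counts per million within each
   condition × replicate × assay sample.
2. `filter_min_barcodes()`: a variant is kept only with ≥ 3 observed
   barcodes in *every* sample ("observed" = count > 0). The filter is
   idempotent.
3. `aggregate_expression()`: expression = Σ normalised RNA / Σ normalised
   DNA over the variant's barcodes, per sample pair.
4. `normalize_to_controls()`: division by the median negative-control
   expression within each condition × replicate. This is a positive
   rescaling, so within-replicate rank order is untouched.
5. `average_replicates()`, `compute_fold_change()`: arithmetic replicate
   mean, then induced/uninduced ratio. A missing condition yields a
   flagged `NA`, never 0.
6. `classify_active()`: active ⇔ expression > median(controls) + 2·MAD,
   where MAD is the raw median absolute deviation without the 1.4826
   consistency factor — the threshold is a descriptive cut, not a Gaussian
   scale estimate. The comparison is strict, so a value exactly at the
   threshold is inactive.

Replicate agreement (`replicate_correlation()`) is reported as Pearson r on
log10 expression by default because expression spans orders of magnitude; a
raw-scale flag exists since either choice is defensible.

## The synthetic-data generator

`simulate_counts()` emulates the structure of the real experiments: two
conditions (0 and 1 mM IPTG) × two biological replicates × {DNA, RNA}, a
truncated-at-1 Poisson number of barcodes per variant (default mean 10, in
the 7–70 range the assays measured), per-barcode Gamma abundance
propensities, and counts drawn by Gamma-perturbing each barcode's rate
(negative-binomial mixing, default size 10) and committing a multinomial
draw at the configured depth (default 10⁶ reads/sample, so sample totals
are exact). True expression is the thermodynamic model prediction times a
lognormal variant × replicate effect (default CV 0.1) shared between the
DNA and RNA assays of a replicate. Dedicated scrambled-operator control
promoters (default 30) express at `r_min`, anchoring control
normalisation.

Ground-truth parameters (`sample_ground_truth()`) are drawn uniformly:
binding energies in [−3, 3] kT for both core pairs and operators, looping
energy in [−4, −1] kT, IPTG penalty in [2, 4] kT, `r_min = 1`,
`r_max` in [200, 400]. The energy band is the regime the libraries actually
probe *and* the regime in which the data identify the parameters; two
structural limits are worth knowing:

* **Strong-core saturation.** Once `exp(-E_core)` dominates every partition
  sum, expression saturates at `r_max` in all states and only an upper
  bound on the core energy is identifiable. Cores beyond about −4 kT are
  in this regime.
* **Weak-operator floor.** An operator with binding energy ≳ +2.5 kT
  represses by less than the count noise, so its energy is only bounded
  below. Individual seeds can therefore show large errors on one or two
  such parameters while fitting the data essentially perfectly, which is
  why recovery is summarised by the median RMSE across seeds.

What the generator does **not** emulate: PCR jackpotting, barcode
sequencing errors and barcode collapsing, read-level artefacts, growth-
condition covariates, and any sequence dependence beyond the part
identities (two variants with the same parts and placements have the same
true expression). Passing recovery tests on this generator therefore shows
the estimator is correct and well-conditioned for data of this structure —
not that real libraries are free of the unmodelled effects.

An optional distal/distal+ interference term (`interaction_kt`) perturbs
the true expression of three-operator variants whose two upstream sites
can both bind. It exists to study, qualitatively, how zero-shot prediction
degrades when the generating process leaves the fitted model family — the
behaviour reported for real three-operator libraries, where interactions
between adjacent upstream sites are not parameterised by the model.

## Fitting

`fit_parameters()` minimises the sum of squared **log10** residuals (the
log transform keeps high expressors from dominating) over:

* one core energy per observed (−35, −10) pair — 16 in the two-operator
  library. The two hexamer energies enter every state only as a sum, so
  per-element additive energies are not separately identifiable and fitting
  the pair sidesteps the gauge;
* one proximal and one distal energy per non-scrambled operator (the
  scrambled operator is pinned at `+Inf`, which together with the rates
  anchors the expression scale);
* the looping energy, the IPTG penalty (when both conditions are present —
  the default is a joint two-condition fit with shared energies), and the
  rates, parameterised as `log r_min` and `log (r_max − r_min)` so the
  ordering constraint holds by construction.

Observed expression ≤ 0 (possible after control normalisation of
near-silent promoters) is floored at half the smallest positive observed
value before taking logs; the floor is configurable.

The optimiser is bounded L-BFGS-B (energies in [−8, 8] kT by default, the
IPTG penalty in [0, 10]) from `n_starts = 10` initialisations: a
data-informed start — core energies backed out of the scrambled-operator
variants through the two-state closed form, proximal energies from median
uninduced repression ratios, distal energies copying the proximal guess —
plus seeded Latin-hypercube draws. Each start runs a short exploration
(60 iterations) and the best is polished to convergence
(`factr` ≈ tolerance/machine-eps, `pgtol = 1e-10`). Everything is
deterministic under the config seed, and the best-objective trace is
recorded (and tested) to be monotone.

Problem sizes used by the shipped checks: the recovery runs simulate the
full 1600-variant two-operator library at default depth and fit 38 free
parameters to 3168 log-expression observations, five seeds for the
recovery summary and one seed for the 5%-train cross-validation and the
2000-variant zero-shot prediction; the whole set completes in a few
minutes on one CPU.

## Landscape and spacing analyses

`expression_grid()`/`fold_change_optimum()` evaluate the fitted model over
operator-energy grids. Optima are located by grid search — matching how
such landscapes are presented and keeping the result trivially auditable —
with edge attainment flagged rather than silently returned, and a
degenerate flag when the surface is flat (`delta_iptg = 0`). Two model
behaviours are tested as acceptance properties: for a strong core and a
finite IPTG penalty the fold-change optimum is strictly interior (operators
can be too strong because some repressor stays active even at saturating
IPTG), and as the core weakens the optimal proximal operator energy rises
in step — repressor strength commensurate with promoter strength.

Spacing profiles use `loess_profile()` (degree-2 local regression, tricube
weights, default span 0.5 — exact on locally polynomial profiles) and
`phase_annotation()`, which flags distal positions whose centre-to-centre
spacing from the proximal site is within 1.5 bp of a whole number of
helical turns (period 10.5 bp, configurable): 3 bp in-phase windows per
turn. `periodicity_fit()` is this package's own construction (and labelled
as such): a least-squares cosine with the period free on a 9–12 bp grid,
with significance from ≥ 1000 permutations of the position labels. It
turns the qualitative 10–11 bp periodicity of looping-mediated repression
into a test statistic; it assumes a single dominant period over at least
two full turns.

`compare_groups()` wraps Welch's t, the two-sided Mann–Whitney U with
Benjamini–Hochberg correction, and a linear-model F test for continuous
covariates such as operator spacing — the three comparisons these analyses
routinely need.

## Known limitations

* The fitted model is an equilibrium occupancy model; systems dominated by
  kinetics (slow repressor exchange, transcriptional bursting) violate its
  assumptions in ways no goodness-of-fit on mean expression will fully
  reveal.
* The distal/distal+ interaction is deliberately not a fitted parameter;
  the package can only demonstrate the *consequence* of such interactions
  (degraded zero-shot accuracy), not estimate them.
* Energies outside roughly [−4, +2.5] kT are one-sidedly identified (see
  the saturation and floor limits above); interpret individual extreme
  estimates with care and prefer the cross-seed medians the tooling
  reports.
* The shipped catalog's TF spacing sites and UP elements are synthetic
  stand-ins; analyses that depend on real operator sequences (e.g. genome
  scans) are out of scope.
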