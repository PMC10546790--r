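---
title: "Steady-state 13C flux analysis of photomixotrophic duckweed growth: models and methods"
author: "lemnaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state 13C flux analysis of photomixotrophic duckweed growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemnaflux)
```

# The scientific problem

Duckweed (*Lemna*) fronds growing on glucose-supplemented liquid medium under
continuous light are *photomixotrophic*: they assimilate organic carbon from
the medium while the Calvin–Benson–Bassham (CBB) cycle simultaneously fixes
CO2. `lemnaflux` implements a complete steady-state ¹³C metabolic flux
analysis (MFA) pipeline for this system: physiological rate equations,
a compartmentalized atom-transition network of central carbon metabolism,
steady-state labeling simulation, weighted least-squares flux estimation with
a χ² goodness-of-fit test, and Monte-Carlo uncertainty with
compartment-aggregated reporting. A synthetic-data generator reproduces the
structure of the underlying labeling experiments so that every stage can be
exercised — and its statistical behaviour verified — without external data.

Two growth regimes are modelled throughout: **INS** (inorganic nitrogen
source, nitrate/ammonium) and **ONS** (organic nitrogen source, 6.85 mM Gln),
which differ in growth rate (0.014 vs 0.019 h⁻¹), glucose uptake
(102.3 vs 80.3 µmol·g-dw⁻¹·h⁻¹) and in the operation of the TCA cycle.

# Physiological rate equations

For an exponentially growing culture the specific growth rate is estimated
from frond-area endpoints, $\mu = (\ln A_t - \ln A_0)/t$, with doubling time
$\ln 2/\mu$. Specific substrate uptake rates follow from medium depletion
relative to dry-weight gain, $v = \frac{S_0 - S}{D - D_0}\,\mu$ (consumption
positive). Because glucose is the only labeled carbon source, the gross
uptake of unlabeled atmospheric CO2 can be computed from the ¹³C enrichment
$f$ of total biomass carbon by inverting the carbon-source mixing relation

$$v_{CO_2} \;=\; \frac{6\,v_{Glc}\,(e_{glc}-f) + 5\,v_{Gln}\,(e_{nat}-f)}{f - e_{nat}},$$

with $e_{glc} = 0.403$ for the 40:60 [U-¹³C₆]:unlabeled glucose design and
natural abundance $e_{nat} = 0.011$. `co2_uptake()` and `f13c_biomass()` are
exact inverses; `resample_co2_uptake()` propagates the input SDs by Gaussian
resampling (infeasible draws with $f \le e_{nat}$ are rejected and redrawn,
which preserves the domain of the rate equation; composition fractions, by
contrast, are truncated at zero to preserve mass positivity).

Biomass sink fluxes are composition-derived: each biomass component
(protein via an amino-acid composition table, cell wall as an anhydroglucose
polymer of monomer weight 162.14 g/mol, starch likewise, lipid as
triacylglycerol split into fatty-acyl C2 units and the glycerol moiety, plus
the major free metabolites) is converted to monomer moles per gram dry
weight and multiplied by $\mu$. The shipped default composition is
reconstructed from the reference sink-flux table at the reference growth
rate, so `biomass_fluxes(default_biomass_composition(cond), mu_ref)`
reproduces that table; users supply their own composition for new data.
Initial dry weights, which are not directly measured, are reconstructed as
$A_0 \times (dw/\text{area})$ — consistent with the observation that the
unlabeled inoculum is about 3% of the harvested biomass.

# The reference network

`build_lemna_core()` constructs a reduced atom-transition model of duckweed
central metabolism (65–68 reactions, 34 balanced metabolites, three
compartments plus merged pools) containing every topological feature the
flux results hinge on:

* glycolysis and the **complete pentose-phosphate pathway duplicated in
  cytosol and plastid** — duckweed genomes lack the xylulose-5-phosphate
  translocator, so the cytosolic oxidative branch is only operable with
  cytosolic regenerative reactions; there is deliberately no
  pentose-phosphate translocator;
* hexose-, triose-, PEP- and PGA-phosphate translocators;
* the CBB cycle with RuBisCO carboxylation and oxygenation and a lumped
  photorespiratory pathway, with a **1000:1 carboxylation:oxygenation ratio
  constraint** (photorespiration suppressed at the elevated internal CO2 of
  photomixotrophic growth);
* the mitochondrial TCA cycle with a merged OAA/Mal pool and an explicit
  50:50 scrambling of the succinate/fumarate-symmetric carbons (paired
  fumarase routes under an exact 1:1 ratio constraint);
* reversible PEP carboxylation (PEPC forward, PEPCK backward, lumped into
  one reversible reaction) — the reaction whose reversal distinguishes the
  two nitrogen regimes;
* Gln uptake, the Gln↔Glu interconversion and Glu↔2-oxoglutarate entry into
  the TCA cycle;
* explicit carbon-skeleton assembly for the measured amino acids Val, Ile
  and Phe (standard biosynthetic carbon origins, e.g. Val from two pyruvates
  minus C1 of the donor), so their GC-MS fragments carry correct positional
  information; the 22 biomass sinks of the reference flux table, named
  exactly as there.

Three CO2-pool configurations address where RuBisCO obtains its substrate:
**A** — a single cellular CO2 pool with net efflux only (no atmospheric
uptake possible); **B** — a separate `CO2_RBC` pool supplying RuBisCO, with
independent atmospheric uptake/release and a freely adjustable reversible
exchange with the cellular pool (solutions range from isolated to quasi-fused
pools); **C** — B plus measurement slots that let the three uptake rates
enter the fit as flux measurements. Open modelling choices resolved here:
the cellular CO2 pool is a single merged pool across compartments (the
compartmental assignment is not resolvable from this data), and the TCA
cycle is strictly mitochondrial.

Networks are serialized in a line-oriented TSV format (`parse_network()`,
`write_network_tsv()`); atom maps assign one lower-case letter per carbon,
educt-side left-to-right starting at C1. `validate_carbon_balance()` checks
atom-multiset conservation for every reaction and reports (rather than
raises) violations. `steady_state_basis()` stacks the stoichiometric
steady-state conditions, fixed fluxes and ratio constraints into one linear
system and returns a particular solution plus an orthonormal null-space
basis, so any parameter vector expands to a flux vector satisfying
$S v = 0$ to 10⁻⁹ relative and the ratio constraints exactly.

# Labeling simulation

`simulate_mids()` computes steady-state mass isotopomer distributions (MIDs)
by EMU (elementary metabolite unit) decomposition: the measured fragments'
carbon subsets are traced backward through the atom maps, and the resulting
EMUs are organized by size into a cascade of linear systems whose matrices
are filled per flux vector and solved densely in compiled code. Reversible
reactions enter as forward/backward pairs with
$fwd = \max(v,0) + xch$, $bwd = \max(-v,0) + xch$. The cascade for the
27-fragment default panel has ~290 EMUs over 7 size levels and evaluates in
well under a millisecond, which is what makes multi-start fitting and Monte
Carlo tractable.

Correctness is established against an independent oracle,
`brute_force_isotopomers()`: full enumeration of every balanced metabolite's
$2^n$ labeling states and damped fixed-point iteration of the complete
isotopomer balance (with per-pool renormalization, which suppresses the
sub-stochastic collapsed fixed points that the bilinear condensation terms
otherwise admit). On the shipped toys and on random flux states of a
single-compartment glycolysis/pentose-phosphate subnetwork the two routes
agree to better than 10⁻⁸.

Numerical choices: fluxes below 10⁻⁹ are treated as zero in the simulator
(clamping them *up* would inject label through structurally inactive
uptakes); an EMU whose total inflow vanishes makes its level system singular
and raises a diagnostic naming the EMU.

# Measurement model and corrections

`mixture_distribution()` expands substrate designs — here 80:10:10
unlabeled : [1-¹³C] : [U-¹³C₆] glucose at 99% isotopic purity, with natural
abundance on unenriched positions — into positional isotopomer
distributions. The computed average enrichment of that mixture is 12.5%
(0.8·6·0.011 + 0.1·(0.99+5·0.011) + 0.1·6·0.99, per carbon); the package
reports the computed value.

Measured fragment mass distributions are corrected in two steps, in this
order: (1) **derivative correction** — the natural isotopologue distribution
of everything beyond the skeleton carbons (TBDMS side chains, Si, etc.,
from a shipped terrestrial abundance table) is deconvolved by nonnegative
least squares on the full convolution matrix, which is stable for long
silicon-rich fragments and exactly inverts forward contamination;
(2) **inoculum correction** — the harvested biomass contains ~3.3% unlabeled
inoculum fronds, so the skeleton MID is un-mixed as
$(m - f\,m_{nat})/(1-f)$, clipped and renormalized.

# Flux estimation

The fit minimizes the variance-weighted sum of squared residuals
$$SSR = \sum_i \left(\frac{sim_i - obs_i}{sd_i}\right)^2 +
        \sum_j \left(\frac{v_j - v_j^{meas}}{sd_j}\right)^2$$
over the free net fluxes and the exchange fluxes of all reversible
reactions. MID standard deviations are floored at 0.01 on the fractional
scale (`apply_sd_floor()`), which eases the goodness-of-fit test at the cost
of wider confidence intervals. Flux measurements enter only on networks that
declare measurable rates (configuration C).

Parameterization. Net fluxes live in the null-space coordinates of
`steady_state_basis()`; bounds are enforced through a smooth quadratic
penalty (reported separately; zero at any interior optimum). Exchange fluxes
are optimized on a bounded transform $x_{01} = xch/(100 + xch)$ — the scale
constant 100 µmol·g-dw⁻¹·h⁻¹ keeps the coordinate well-resolved for the
large CO2-pool exchange fluxes (150–400 in flux units) this system needs.

Search strategy. Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, iteration cap 2000 mapped to the implementation
ceiling of 1024) is restarted from `n_restarts` random points: uniform draws
in the truncated net-flux bound box projected onto the steady-state space,
with $x_{01} \sim U(0.02, 0.8)$; starts that land in a singular labeling
system are resampled. Because the SSR landscape has long sloppy valleys, the
incumbent is then refined by a deterministic polish phase: repeated LM runs
from the incumbent plus jittered copies whose scale cycles through
coarse-to-fine values, so the search can both cross near-degenerate
circulation modes (e.g. a flux loop around the PGA/PEP translocators whose
members all carry identity atom maps) and settle the sloppy directions.
On noise-free synthetic data this recovers the generating flux state to
machine precision (SSR ≈ 10⁻¹⁷, all fluxes of magnitude > 1 to better than
10⁻³ relative). Everything is deterministic given `seed`.

Model acceptance uses the χ² rule: degrees of freedom = (MID entries) −
(measurement groups, one per fragment) + (flux measurements) − (free net +
free exchange fluxes); a solution is accepted at the 90% confidence level
iff $SSR \le \chi^2_{0.9}(dof)$, boundary inclusive. Measurement-group scale
factors are not fitted. `find_alternative_optima()` profiles a single flux
across a pinned grid with re-optimization, exposing structurally
undetermined splits — the cytosolic/plastidic division of the oxidative
pentose-phosphate flux being the canonical example: either compartment's
reaction can be driven toward zero with little SSR cost while their *sum*
is tightly bounded.

# Monte-Carlo uncertainty and aggregation

`monte_carlo()` corrupts the corrected MIDs and the measured rates with
Gaussian noise at their reported SDs (clipped, renormalized), re-fits each
replicate (warm-started at the base fit plus random restarts), and uses the
spread of the best-fit vectors as the flux uncertainty (sample SD, n−1
denominator). Noise uses the reported SDs rather than the floored ones so
that zero-noise ensembles collapse exactly onto the base fit; in the study
design the reported MID SD equals the floor (0.01) anyway.

Because compartment splits are poorly resolved, results are reported on the
uncompartmentalized view: `aggregation_map()` adds fluxes of reactions
connecting the same metabolite pair in different compartments (e.g. combined
OPPP oxidative flux = vG6PDH_c + vG6PDH_p) and maps transporters between
merged pools to zero rows. Aggregation is linear, so it is applied to every
ensemble member and the member spread directly yields the combined flux's
SD — anticorrelated degenerate splits combine into a much tighter total.
`flux_ratio()` works the same way for ratios (e.g. OPPP decarboxylation over
RuBisCO carboxylation), and `atmospheric_fraction()` reports, in the
forward-flux formulation, the share of the RuBisCO CO2 pool supplied by
atmospheric uptake versus forward exchange from the cellular pool.

# The synthetic-data generator

`scenario_preset()` bundles the measured study conditions: uptake rates and
the 22 sink fluxes with their SDs, the 80:10:10 labeling design, Gaussian
measurement noise of SD 0.01 on the fractional scale (the same magnitude as
the fitting floor), and the 3.3% inoculum fraction. `truth_flux()` fixes the
uptakes and sinks at their printed values and places the remaining free
fluxes at a documented operating point by weighted least squares: combined
OPPP flux at 0.60 of RuBisCO carboxylation (split 30/98.1 under INS),
PEP carboxylation forward under INS and reversed under ONS, atmospheric
share of the RuBisCO CO2 supply 0.58 (INS) / 0.60 (ONS), plus weak anchors
(vG6Pt = 60, vTPt = −20, vPGAt = 10, vPK_c = 20) that select a feasible
interior point among the remaining directions. Exchange fluxes are drawn
once from a seeded U(5, 25), except the CO2-pool exchange which is set to
realize the atmospheric share exactly. `generate_measurements()` then runs
the forward measurement model (simulate → inoculum mixing → derivative
convolution → seeded noise, clipped and renormalized) and the correction
chain in reverse; corrected-scale SDs are obtained by linear propagation of
the raw-scale noise through the deconvolution.

What the generator does *not* emulate: analyte-specific measurement biases,
fragment cross-contamination, drift between batches, biological variation in
the atom maps, or metabolic channeling — so passing recovery tests shows
self-consistency of the whole pipeline at the study's operating point and
noise level, not robustness to the full error structure of real GC-MS data.

# Statistical calibration — what to expect

Measured MID vectors are normalized to sum to one. Adding independent
Gaussian noise and renormalizing makes the per-fragment residual vector
(weighted by the nominal SD) follow a *projected* normal whose total
variance is $n_f - 2 + n_f \sum_j \mu_j^2$ rather than the $n_f - 1$ the
degrees-of-freedom rule books. The two coincide exactly for uniform MIDs
($\sum_j \mu_j^2 = 1/n_f$) and diverge for near-delta MIDs, where the χ²
test becomes conservative (SSR runs above its nominal reference, acceptance
below the nominal 90%). On the realistic 27-fragment panel the inflation is
small (~6% in SSR at truth). The package's calibration study therefore runs
on a two-pool exchange toy with ~50% per-position enrichment — near-uniform
MIDs and a single, labeling-effective fitted parameter — where the DOF rule
is exact and the observed acceptance rate (86% over 50 seeded replicates)
is compatible with the nominal level.

# Problem sizes used in the shipped studies

The packaged tests and the acceptance script run scaled-down versions of the
full protocol, chosen as the smallest sizes at which each conclusion is
stable: oracle equivalence on 20 random flux states; noise-free recovery
with 10 restarts plus 8 polish rounds; Monte Carlo with 10 replicates × 20
restarts (the full protocol is 20 × 50, and 100 restarts for a final fit);
χ² calibration over 50 replicates; configuration comparison with 6–8
restarts per configuration. All are deterministic under their seeds.

# Known limitations

* Isotopically nonstationary labeling (¹³CO2 pulse designs) is out of scope;
  the model is strictly steady-state.
* The reduced network stands in for the full genome-derived reconstruction;
  gene associations, SBML exchange and genome-based network building are not
  provided.
* Exchange fluxes of reactions with identity atom maps between pools of
  identical labeling (e.g. PGA ↔ PEP within one compartment) are
  structurally label-inert: they are counted as free parameters by the DOF
  rule but cannot be determined by any labeling data.
* Linearized (covariance-matrix) confidence intervals are not implemented;
  uncertainty comes from Monte Carlo and profile continuation only.
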