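---
title: "Projecting chronic-disease prevalence with impactdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting chronic-disease prevalence with impactdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactdm)
```

## The model

`impactdm` implements a discrete-time Markov cohort model for projecting the
prevalence of type 2 diabetes in an adult population, in the style of the
MEDCHAMPS IMPACT family of policy models. Within each stratum (sex × 10-year
age band, ages 25 and over) the living population occupies five mutually
exclusive compartments:

* four **starting states** partitioning the non-diabetic pool by exposure:
  healthy (non-obese non-smoker), obese only, smoker only, obese smoker;
* a **diabetes** state.

Two absorbing states — death from diabetes-related causes and death from
other causes — capture competing mortality risks. Each cycle lasts one year.
There is **no remission**: the only outflow from the diabetes state is to
death. Annual transition probabilities into diabetes differ by starting
state through incidence relative risks; every living compartment is subject
to background mortality, and the diabetes compartment additionally to an
excess mortality hazard.

Overlap between exposures is handled by assuming independence of obesity
and smoking within a stratum's non-diabetic pool: the pool splits into
shares $(1-q_o)(1-q_s),\; q_o(1-q_s),\; (1-q_o)q_s,\; q_o q_s$, which
reproduce the marginal exposure prevalences exactly. Users with joint
prevalence data can supply their own split by constructing states directly.

### Within-cycle order of operations

The order is fixed and pinned, because changing it changes results:

1. deaths leave every living compartment;
2. incident cases move from the exposure compartments to diabetes;
3. band aging advances a fraction $1/w$ of every living compartment ($w$ =
   band width in years; none out of the open-ended oldest band);
4. entrants join the youngest band diabetes-free, and (in anchored mode)
   living band populations are reconciled to the external trajectory;
5. the non-diabetic pool is re-split to the trend-updated exposure
   prevalences.

Step 5 moves people between exposure compartments only; it never creates or
destroys diabetes cases.

### Demography: anchored and closed modes

The published population projections that drive models of this kind encode
birth-cohort effects (for instance a band that triples while its neighbours
merely double) which the $1/w$ aging approximation cannot reproduce from
within. The engine therefore runs by default in **anchored** mode: diabetes
cases evolve mechanistically (deaths, incidence, band aging) while the
living population of each band follows the externally supplied trajectory,
interpolated geometrically (constant annual growth per stratum) between
anchor years. The non-diabetic pool absorbs the demographic change — a
reasonable assumption because population growth enters at young,
overwhelmingly disease-free ages. Entrants per sex are defined as the
top-up reconciling survivors with the anchored total, so the per-sex
accounting identity

$$\text{living}(t{+}1) + \text{cumulative deaths}(t{+}1) =
  \text{living}(t) + \text{cumulative deaths}(t) + \text{entrants}$$

holds to machine precision at every cycle (it is asserted in the test
suite). A **closed** mode with no reconciliation (population evolves by
deaths and aging only) exists for validation: with a single stratum and
constant hazards the engine must match, and does match to within 0.1%, the
closed-form solution of the two-compartment illness–death recursion.

Anchors themselves can be reconstructed from published report tables: a
cell printing "cases (prevalence%)" implies the denominator
`count / (prevalence/100)`. `reconstruct_denominators()` does this per
band; totals rows are deliberately not used as denominator sources (they
serve as checksums). Printed prevalences are rounded to one decimal, so
reconstructed denominators carry a relative uncertainty of roughly
$0.05/p$ — about 4% in a band printed at 1.2%, under 0.2% at 27%. This
uncertainty is why the reproduction checks in the test suite use tolerance
bands rather than exact equality.

## Estimating rates from a prevalence survey

A cross-sectional prevalence curve, an all-cause mortality schedule and a
mortality rate ratio are enough to recover the age-specific incidence and
excess mortality of a chronic, non-remitting disease.

**Mortality partition.** Given all-cause mortality $m$, prevalence $p$ and
the mortality rate ratio $RR$ of diseased vs non-diseased (Barendregt's
method), background and diseased mortality follow in closed form:
$m_0 = m / (1 - p + p\,RR)$, $m_1 = RR\, m_0$, and the excess hazard is
$e = m_0 (RR - 1)$.

**Incidence back-calculation.** A synthetic single-year cohort is swept up
the age axis under the recursion
$$S' = S(1 - i - m_0), \qquad C' = C(1 - m_0 - e) + S\,i,$$
with remission fixed at zero, and the constant within-band incidence $i$
is solved by bisection (tolerance $10^{-10}$, 200-iteration cap,
robustness preferred over speed at this scale) so that $C/(S+C)$ matches
the observed prevalence at the band midpoint. Band-level hazards apply
uniformly to all single years within a band. Where the observed curve
falls faster than excess mortality can explain, no non-negative incidence
fits; the estimate is floored at zero with a diagnostic. This is a
transparent re-implementation of the generic illness–death consistency
logic found in the DisMod II tradition; it makes no attempt to reproduce
that software's internal smoothing, and differences from it are absorbed
by the tolerance bands of the reproduction tests.

The estimator and the forward simulator `prevalence_from_rates()` are
exact inverses: round-trip tests recover a constant generating incidence
to better than 1% and reproduce arbitrary prevalence curves to better than
0.5 percentage points.

## Parameters of the Syria preset

The shipped preset (`syria_preset()`) projects diabetes among Syrian
adults 25+ over 2003–2022. Its parameters, all overridable through the
YAML config:

| parameter | default | units | rationale |
|---|---|---|---|
| baseline diabetes prevalence | published 2003 band cells | proportion | survey-derived, under-diagnosis already incorporated |
| obesity baseline | 0.29 (M) / 0.401 (F) | proportion | 2003 national risk-factor survey |
| smoking baseline | 0.591 (M) / 0.188 (F) | proportion | idem |
| obesity trend | +1.0 pp/yr (+0.2 for ages 25–34) | percentage points/yr | extrapolation of local data; absolute scale, since the ceiling below is absolute |
| obesity cap | 0.80 | proportion | assumed saturation of the obesity epidemic |
| smoking trend | 0 | pp/yr | no-change expert consensus |
| incidence | 1190 (M) / 1570 (F) | per 100,000/yr | published national illness-death estimates for 2003, applied uniformly over bands (below) |
| `rr_mort_dm` | 1.42 | ratio | Verona Diabetes Study cohort (all-cause SMR) |
| `rr_dm_obese` | 7.19 | ratio | Abdullah et al. 2010 meta-analysis, obese vs normal weight |
| `rr_dm_smoker` | 1.44 | ratio | Willi et al. 2007 meta-analysis, active smokers |
| all-cause mortality | per-band schedule in `syria_mortality.csv` | per person-yr | approximates the UN schedule for Syria around 2003 |

The under-diagnosis multiplier (`adjust_underdiagnosis()`, default 1.5,
capped at 1) is a data-preparation step for raw self-reported prevalence;
the preset's band cells already reflect it.

**Why age-uniform incidence?** The package supports three incidence
sources: a per-band table, back-calculation from the baseline curve
(`type = "estimate"`), and a sex-level rate applied uniformly over bands
(`type = "uniform_by_sex"`, the preset default). The choice matters. An
age-specific incidence back-calculated from the 2003 curve places the 2003
population close to its own steady state, so band prevalences barely move
and all subsequent growth is demographic. The published projection this
preset emulates behaves differently — young-adult prevalence rises
roughly tenfold while prevalence in older women *declines* — and both
features emerge naturally when each sex's crude incidence is applied
uniformly across bands: young bands are far below the steady state this
incidence implies (so they climb steeply), and the oldest female bands are
above it (so they drift down as lower-prevalence cohorts age in). The
preset therefore supplies the published sex-level rates as direct inputs.
The time path of incidence is then driven by the risk-factor trends: the
healthy-reference rate is calibrated once at baseline
($i_{\mathrm{ref}} = i_{\mathrm{pop}} / \sum_g \mathrm{share}_g RR_g$,
joint obese-smoker risk multiplicative by default, `"max"` available) and
held fixed, so the population rate moves exactly with the exposure mix.

### Intervention scenarios

A prevention program is specified by a start year, a phase-in duration, and
relative reductions in obesity and smoking prevalence, applied to the
non-diabetic pools only and phased in linearly. Two readings of "target a
fraction of each pool for a reduction" are implemented:

* **population-wide** (preset default): the stated reductions apply to the
  whole exposure pools — multiplier $1 - r \cdot \mathrm{phase}(t)$;
* **targeted**: only the targeted fraction achieves the reduction —
  multiplier $1 - f \cdot r \cdot \mathrm{phase}(t)$.

The population-wide reading is the default because it is the one that
reproduces the published scenario checkpoints this preset is validated
against; under the targeted reading the preset's 10%/40%/20% targeting
fractions dilute the reductions to a few percent of incidence, visibly too
weak for those checkpoints. The targeted fraction of the *healthy* pool is
parsed and stored but has no effect under either reading — healthy people
carry no exposure to reduce.

Scenario invariants asserted in the tests: a zero-reduction scenario is
bit-identical to the baseline; stronger reductions never yield higher
prevalence in any year; cases averted grow monotonically for the preset's
scenario shape.

## The synthetic-country generator

`synthetic_country_spec()` / `generate_country()` produce complete,
internally consistent input bundles with known ground truth: constant
hazards per stratum (so the implied band-midpoint prevalence curve follows
the closed-form recursion exactly), geometric population growth between
two anchor years, exposure baselines and trends, and an all-cause
mortality schedule consistent with the generating hazards
($m = (1-p) m_0 + p (m_0 + e)$). Default dimensions are three bands × two
sexes over a 20-year horizon — small enough that the full
generate → estimate → project → compare loop runs in well under a second,
which is what lets the test suite afford 100-replicate noise studies.

`perturb_bundle()` applies multiplicative lognormal noise to the input
tables (never to the engine, which stays deterministic); proportions are
clipped back to $[0,1]$. With $\sigma = 0.05$ over 100 replicate seeds the
back-calculated incidence is unbiased to within Monte-Carlo error.

What the generator does *not* emulate: survey sampling designs, age-varying
hazards (an age-varying preset exists for qualitative tests only, since
only constant hazards admit the closed form), migration, and fertility.
Passing the synthetic tests therefore demonstrates correctness of the
arithmetic and the estimators, not realism of any particular national
configuration.

## Numerical choices and degenerate inputs

* Geometric interpolation degenerates when an anchor count is zero; the
  affected interval falls back to linear interpolation.
* Extrapolation beyond the anchor span is refused rather than guessed.
* Bisection for incidence runs on $i \in [0, 1]$ with tolerance
  $10^{-10}$; non-convergence (not observed in practice) is an error
  naming the offending band.
* Hazards may enter as annual probabilities (used directly, the preset
  default, appropriate when inputs are already cycle probabilities) or as
  true hazards (converted by $1 - e^{-h}$).
* Negative entrant counts (shrinking youngest band beyond deaths and
  aging) are floored at zero with a warning in `cohort_entry()`;
  the anchored engine reports the signed top-up it actually used.
* Zero-population strata keep prevalence defined as 0.
* Cells printing zero cases at zero prevalence have unknown denominators
  and are flagged `NA` rather than imputed.

## Reporting conventions

`tabulate_report()` reproduces the "count (prevalence%)" layout with
counts rounded to integers, prevalence to one decimal, and totals rows
recomputed from unrounded values. The 20–79 comparison view
(`idf_comparable()`) removes the >79 share of the open-ended band —
default split 0.5, applied consistently to both cases and population for
both sexes — and adds a 20–24 population at zero prevalence. The split
and the zero-prevalence assumption are deliberate simplifications; the
package reports its own internally consistent values rather than
reproducing known rounding artifacts of any published table.

## Known limitations

* Only obesity and smoking drive incidence differentials; physical
  activity, diet and urban/rural structure are out of scope.
* The $1/w$ band-aging approximation exchanges single-year cohort
  resolution for a 12-stratum state space; anchored mode compensates at
  the population level but not within the diabetic pool, whose age
  composition inside a band is not tracked.
* Mortality relative risk is age-constant; age-varying schedules would
  need only a vectorised `rr_mort` but published single values rarely
  support more.
* Point estimates only: no uncertainty propagation beyond the synthetic
  noise studies.

## Problem sizes

Every check in the test suite runs the full pipeline at its natural scale:
the national preset is 12 strata × 20 years (a single projection takes a
few hundredths of a second), and synthetic studies use 6 strata × 20
years × up to 100 noise replicates. Nothing is down-sampled.
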