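# impactdm

Discrete-state Markov projection of type 2 diabetes prevalence for
age/sex-stratified adult populations, with illness–death estimation of
incidence and diabetes-related mortality from cross-sectional prevalence,
risk-factor trend rules, and counterfactual prevention-program scenarios.

The package is written for epidemiologists and health planners who need a
transparent, fully testable implementation of the MEDCHAMPS IMPACT-style
diabetes model: a population split into mutually exclusive starting states
— healthy, obese-only, smoker-only, obese-smoker — plus a diabetes state
with no remission and two absorbing death states (diabetes-related and
other), advanced in one-year cycles.

## The model in brief

Within each stratum (sex × 10-year band, ages 25+):

* the non-diabetic pool splits under independence into exposure shares
  *(1−q_o)(1−q_s), q_o(1−q_s), (1−q_o)q_s, q_o·q_s*;
* annual incidence per exposure state is *i_ref · RR_g*, with the
  reference rate calibrated so the share-weighted mean equals the
  population incidence: *i_ref = i_pop / Σ share_g RR_g*;
* all-cause mortality *m* is partitioned by disease status via the
  Barendregt closed form *m₀ = m / (1 − p + p·RR)*, *m₁ = RR·m₀*, giving
  the excess hazard *e = m₀(RR − 1)*;
* age-specific incidence can be back-calculated from a prevalence curve
  with the zero-remission illness–death recursion
  *S′ = S(1 − i − m₀)*, *C′ = C(1 − m₀ − e) + S·i*, solved per band by
  bisection at band midpoints;
* risk-factor trends move exposure prevalences in absolute percentage
  points per year (obesity capped at 80%), and intervention scenarios
  multiply them by phased reduction factors.

See `vignettes/diabetes-projection.Rmd` for the full account, including
the anchored-demography design and the incidence-source options.

## Worked example: the Syria 2003–2022 preset

```r
library(impactdm)

cfg  <- syria_preset()          # published report cells + documented config
proj <- run_projection(cfg)
proj
#> <impact_projection> 2003-2022, 12 strata
#>   prevalence 2003: 10.1% (686,195 cases)  ->  2022: 19.7% (2,727,791 cases)
```

The projection starts from the 2003 baseline (10.1% prevalence among
adults 25+, 686,195 people) and roughly doubles prevalence by 2022 as the
population grows, ages, and obesity trends upward. Report tables use the
familiar "count (prevalence%)" layout:

```r
tabulate_report(proj, years = c(2003, 2011, 2022))
#>    sex   band  2003          2011           2022
#>  1 M     25-34 16995 (1.2)   113547 (5.2)   192604 (8.7)
#>  ...
#>  7 M     total 262501 (7.7)  567828 (10.8)  1196598 (17.1)
#> 14 F     total 423694 (12.4) 796740 (15.3)  1531193 (22.5)
#> 15 all   total 686195 (10.1) 1364568 (13.1) 2727791 (19.7)
```

Prevalence rises most steeply in the youngest bands (men 25–34 go from
1.2% to 8.7%, an ~11.5-fold increase) while the oldest female bands move
little — both signatures of a sex-level incidence acting on a young,
growing population. The hypothetical 10-year prevention program (25%
obesity and 50% smoking reduction, phased 2003–2012):

```r
compare_scenarios(proj, run_scenario(cfg), years = c(2013, 2022))
#>  year prevalence_baseline prevalence_intervention pp_difference relative_reduction_pct cases_averted
#>  2013               14.48                   13.12          1.36                    9.4        149394
#>  2022               19.75                   16.54          3.20                   16.2        442628
```

i.e. about 0.44 million diabetes cases averted by 2022 under the preset
configuration.

Synthetic data with known ground truth for validation:

```r
b <- generate_country(synthetic_country_spec(incidence = 0.02))
est <- estimate_incidence_from_prevalence(
  b$prevalence$prevalence[1:3], b$truth$m0[1:3], b$truth$excess[1:3],
  age_lower = c(25, 35, 45), age_upper = c(35, 45, 55)
)
est$incidence        # recovers 0.02 to <1%
```

A thin command-line wrapper (`inst/cli/impactdm.R`) exposes `project`,
`rates`, `scenario` and `synth` subcommands over the same functions.

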