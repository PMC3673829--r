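# Master configuration for the Syria 2003-2022 diabetes projection preset.
#
# File paths are resolved relative to this file. Rates are annual
# probabilities ("probability") or per-person-year hazards ("hazard").

horizon:
  start: 2003
  end: 2022

demography:
  # Per-band population denominators are reconstructed at each report year
  # from the published "count (prevalence%)" cells and interpolated
  # geometrically between those anchor years.
  report_csv: syria_table1.csv
  population_csv: ~        # alternative: direct year/sex/band counts
  mode: anchored           # anchored | closed

rates:
  rate_type: probability
  mortality_csv: syria_mortality.csv   # all-cause, per person-year;
                                       # approximates the UN schedule for
                                       # Syria around 2003
  # Sex-level population incidence applied uniformly over age bands and
  # scaled over time by the exposure-mix relative-risk factor. The values
  # are the published national illness-death estimates for 2003.
  # Alternatives: {type: estimate} back-calculates age-specific incidence
  # from the baseline prevalence curve; or supply a per-band CSV.
  incidence:
    type: uniform_by_sex
    per_100k:
      M: 1190
      F: 1570

relative_risks:
  mort_dm: 1.42    # all-cause mortality, diabetic vs non-diabetic
                   # (Verona Diabetes Study cohort)
  dm_obese: 7.19   # diabetes incidence, obese vs non-obese
                   # (Abdullah et al. 2010 meta-analysis)
  dm_smoker: 1.44  # diabetes incidence, active smokers vs non-smokers
                   # (Willi et al. 2007 meta-analysis)
  joint: multiplicative   # multiplicative | max

risk_factors:
  obesity:
    baseline: {M: 0.29, F: 0.401}
    trend_pp_per_year: 1.0   # absolute percentage points per year
    trend_pp_young: 0.2      # the youngest band trends more slowly
    cap: 0.80                # obesity prevalence ceiling
  smoking:
    baseline: {M: 0.591, F: 0.188}
    trend_pp_per_year: 0.0   # no-change assumption

scenario:
  # Hypothetical 10-year prevention program starting at baseline.
  start_year: 2003
  duration: 10
  obesity_reduction: 0.25
  smoking_reduction: 0.50
  target_fractions: {healthy: 0.10, obese: 0.40, smoker: 0.20}
  reading: population_wide   # population_wide | targeted
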