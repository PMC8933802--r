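# Default hospital scenario: a small hospital of 3 specialty wards with 40
# beds each, 3 illnesses x 3 severities, 7 stochastic arrivals per day,
# geometric length of stay with mean 14 days, 10-day sessions, and a
# physician specialty-acceptance multiplier uniform on [1.0, 2.0].
illnesses: [gastric ulcer, pneumonia, heart failure]
severities: [mild, moderate, severe]
weights:
  matched:    {mild: 1.0, moderate: 1.25, severe: 1.5}
  # mismatched admissions carry a surcharge; the shipped moderate value is
  # 1.8 (use 1.875 for an exact +50% at every severity)
  mismatched: {mild: 1.5, moderate: 1.8, severe: 2.25}
wards:
  - {id: A, specialty: gastric ulcer, capacity: 40}
  - {id: B, specialty: pneumonia, capacity: 40}
  - {id: C, specialty: heart failure, capacity: 40}
arrivals_per_day: 7
mean_los_days: 14
n_days: 10
multiplier_range: [1.0, 2.0]
# arrivals are uniform over the 9 (illness, severity) patterns when
# arrival_distribution is omitted
policies:
  default: {kind: constant, base: 5}
discharge_timing: day_end
show_other_prices: false
seed: 1
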