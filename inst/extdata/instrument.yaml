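days_per_month: 30.4
food_frequency:
  - label: never
    times_per_month: 0.0
  - label: 1 time per month or less
    times_per_month: 0.5
  - label: 2-3 times per month
    times_per_month: 2.5
  - label: 1-2 times per week
    times_per_month: 6.514285714285714
  - label: 3-4 times per week
    times_per_month: 15.2
  - label: 5-6 times per week
    times_per_month: 23.885714285714286
  - label: 1 time per day
    times_per_month: 30.4
  - label: 2 or more times per day
    times_per_month: 60.8
beverage_frequency:
  - label: never
    times_per_month: 0.0
  - label: 1 time per month or less
    times_per_month: 0.5
  - label: 2-3 times per month
    times_per_month: 2.5
  - label: 1-2 times per week
    times_per_month: 6.514285714285714
  - label: 3-4 times per week
    times_per_month: 15.2
  - label: 5-6 times per week
    times_per_month: 23.885714285714286
  - label: 1 time per day
    times_per_month: 30.4
  - label: 2-3 times per day
    times_per_month: 76.0
  - label: 4-5 times per day
    times_per_month: 136.8
  - label: 6 or more times per day
    times_per_month: 182.4
condiment_fraction:
  - label: almost never or never
    fraction: 0.0
  - label: about 1/4 of the time
    fraction: 0.25
  - label: about 1/2 of the time
    fraction: 0.5
  - label: about 3/4 of the time
    fraction: 0.75
  - label: almost always or always
    fraction: 1.0
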