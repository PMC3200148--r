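# Sensitivity-scenario presets: discount-rate variants (annual fractions,
# health/costs) and time-horizon variants (years or "lifetime").
- label: "0%/0%"
  rate_health: 0.0
  rate_cost: 0.0
- label: "base 1.5%/4%"
  rate_health: 0.015
  rate_cost: 0.04
- label: "4%/4%"
  rate_health: 0.04
  rate_cost: 0.04
- label: "health 0%/costs 4%"
  rate_health: 0.0
  rate_cost: 0.04
- label: "lifetime"
  horizon: lifetime
- label: "50y"
  horizon: 50
- label: "25y"
  horizon: 25
- label: "without capacities"
  capacities_active: false
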