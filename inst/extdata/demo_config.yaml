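# Demonstration run: a synthetic multi-site OSCE shaped like a six-site
# exam with four forms and eighteen stations, persons nested within sites.
# The true variance components are illustrative values chosen so the
# dependability coefficient of the current configuration lands near 0.8;
# they are NOT estimates from any real examination.
design: "p:s x f x st"
error_type: absolute

scores:
  simulate:
    sizes: {p: 50, s: 6, f: 4, st: 18}   # p = persons per site
    grand_mean: 70
    components:
      "p:s": 0.30        # universe-score variance (persons within sites)
      "s": 0.05
      "f": 0.08
      "st": 0.45
      "s*f": 0.02
      "s*st": 0.05
      "f*st": 0.10
      "s*f*st": 0.02
      "p*f:s": 0.15
      "p*st:s": 1.20
      "p*f*st:s": 2.00   # residual
    seed: 20260401

plans:
  current:  {s: 6, f: 4, st: 18}
  proposal: {s: 5, f: 3, st: 17}

costs:
  currency: GBP
  unit_costs: {s: 15896, f: 6677, st: 4843}
  fixed_cost: 0

cea:
  base: current
  intervention: proposal
  rescale_unit: 0.01
  uncertainty:
    effectiveness: {dist: normal, sd: 0.01}
    cost: {dist: normal, cv: 0.10}
  n_draws: 10000
  seed: 20260402
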