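# Reproduction of the published ICER arithmetic for a six-site OSCE cost
# reduction proposal.  Costs and effectiveness values are direct inputs
# (the underlying performance data are unpublished): current plan
# 209,240 GBP at dependability 0.81, proposal 147,491 GBP at 0.75.
design: "p:s x f x st"
error_type: absolute

plans:
  current:  {s: 6, f: 4, st: 18}
  proposal: {s: 5, f: 2, st: 17}

costs:
  currency: GBP
  unit_costs: {s: 15896, f: 6677, st: 4843}
  totals: {current: 209240, proposal: 147491}   # published totals

cea:
  base: current
  intervention: proposal
  effectiveness: {current: 0.81, proposal: 0.75}
  rescale_unit: 0.01
  uncertainty:
    effectiveness: {dist: normal, sd: 0.01}
    cost: {dist: normal, cv: 0.10}
  n_draws: 10000
  seed: 20260403
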