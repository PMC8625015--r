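# Per-site deuterium incorporation probabilities by functional-group class,
# calibrated for the reference spray condition (methanol/D2O 7:3 v/v, no
# extra back exchange). The ordering hydroxyl > phenol encodes the faster
# liquid-phase exchange of aliphatic hydroxyls relative to phenols;
# charge_site is the probability that the charging proton of a
# proton-bearing adduct leaves the source as a deuteron.
exchange_probability:
  hydroxyl: 0.45
  phenol: 0.20
  amine: 0.50
  imine_NH: 0.50
  amide_NH: 0.30
  carboxyl: 0.60
  charge_site: 0.25
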