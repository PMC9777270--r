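# Default mechanical and transport constants with their original published
# units declared; load_parameters() converts everything to m / day / Pa.
mechanics:
  phi: 0.2
  K: {value: 40000, unit: Pa}
  G: {value: 30000, unit: Pa}
  alpha: 0.7
  kappa: {value: 6.9e-14, unit: m2.Pa-1.s-1}
  M_biot: {value: 2.0e+5, unit: Pa}
  # average human blood pressure (~90 mmHg); all outputs are invariant to it
  p0: {value: 1.2e+4, unit: Pa}
transport:
  D_cell: {value: 3.6e-8, unit: cm2.h-1}
  D_cyto: {value: 5.2e-5, unit: cm2.h-1}
  D_H: {value: 3.3e-3, unit: cm2.h-1}
  b: 1
species:
  # solid-cell size weights (area per scaled unit) for Dn, D, C, N;
  # only volume ratios V/V0 are reported, so the common scale is free
  A: {Dn: 1, D: 1, C: 1, N: 1}
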