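REMARK  synthetic test solute: one rigid three-site water (TIP3P-like
REMARK  geometry and charges; radii chosen so the default radius->sigma
REMARK  convention reproduces the model LJ diameters)
ATOM      1  O   WAT     1       0.000   0.000   0.000 -0.8340 1.7683
ATOM      2  H1  WAT     1       0.757   0.000   0.586  0.4170 0.6938
ATOM      3  H2  WAT     1      -0.757   0.000   0.586  0.4170 0.6938
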