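REMARK  synthetic test solute: one neutral Lennard-Jones sphere
REMARK  columns: record serial name res resid x y z charge radius
ATOM      1  LJ  SPH     1       0.000   0.000   0.000  0.0000 1.7680
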