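# Standard formation free energies (kJ/mol) of the net-reaction species.
O2: 231.7
H2O: -237.1
H+: 0.0
O2-: 33.8
H2O2: -120.4
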