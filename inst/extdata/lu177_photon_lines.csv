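energy_kev,intensity
71.64,0.00172
112.95,0.0617
136.72,0.00047
208.37,0.1036
249.67,0.00212
321.32,0.00219
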