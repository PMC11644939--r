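class,density_g_per_mm3
rice,0.00085
chicken,0.00105
fries,0.00055
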