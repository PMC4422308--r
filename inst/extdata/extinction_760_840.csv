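wavelength_nm,eps_hbo2,eps_hbr
760,0.0586,0.15485
840,0.1058,0.07819
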