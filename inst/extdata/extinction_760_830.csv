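wavelength_nm,eps_hbo,eps_hbr
760,0.000586,0.00154852
830,0.000974,0.00069304
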