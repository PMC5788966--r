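wavelength_nm,eps_hbo,eps_hbr
690,276.0,2051.96
760,1486.5865,3843.707
780,735.4,1106.2
808,856.0,799.6
830,974.0,693.04
850,2526.391,1798.643
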