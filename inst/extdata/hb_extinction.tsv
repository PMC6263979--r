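# Molar extinction coefficients of human hemoglobin, cm^-1 / (mol/L)
# Representative compiled literature values on a coarse NIR grid.
# wavelength_nm	eps_hbo2	eps_hb
650	368.0	3750.12
680	406.0	2731.60
700	446.0	1794.28
750	518.0	1405.24
760	586.0	1548.52
780	710.0	1075.44
800	816.0	761.72
805	840.0	740.00
850	1058.0	691.32
900	1198.0	761.84
950	1204.0	602.00
1000	1214.0	504.00
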