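ligand,ph,dG_gas,dG_sol,dG_mmpbsa_printed,minus_TdS,dG_bind_printed
farnesene,7.4,-37.29,7.58,-29.71,78.45,-48.74
caryophyllene,7.4,-36.71,7.31,-29.40,78.69,-49.29
octenol,7.4,-25.99,7.45,-18.54,26.99,-8.45
farnesene,5.5,-36.01,6.39,-29.62,75.93,-46.31
caryophyllene,5.5,-36.67,7.55,-29.12,74.21,-45.09
octenol,5.5,-24.79,8.24,-16.55,23.14,-6.59
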