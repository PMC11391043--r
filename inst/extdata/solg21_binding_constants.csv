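quantity,ligand,ph,value_uM
Kd,1-NPN,7.4,2.33
Kd,1-NPN,5.5,4.83
Ki,farnesene,7.4,0.72
Ki,caryophyllene,7.4,1.06
Ki,octenol,7.4,2.00
Ki,farnesene,5.5,1.24
Ki,caryophyllene,5.5,15.99
Ki,octenol,5.5,5.61
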