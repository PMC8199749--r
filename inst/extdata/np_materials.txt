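# Nanoparticle material library: eleven metal and metal-oxide compositions
# surveyed at 10 mg/mL in water.
name formula
Cu Cu
ZrO2 ZrO2
Ag Ag
CeO2 CeO2
Gd2O3 Gd2O3
Tm2O3 Tm2O3
HfO2 HfO2
Ta2O5 Ta2O5
Bi2O3 Bi2O3
Pt Pt
Au Au
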