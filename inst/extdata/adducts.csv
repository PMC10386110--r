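# Default positive-mode ESI adduct set.
# mass_shift is the Da added to the neutral molecule before dividing by charge;
# shifts include the electron term (e.g. +H uses the proton mass 1.00727646688,
# +Na uses Na minus one electron), which matters at sub-mDa tolerances.
label,mass_shift,charge
[M+H]+,1.00727646688,1
[M+Na]+,22.98922070,1
[M+NH4]+,18.03382555,1
[M+K]+,38.96315810,1
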