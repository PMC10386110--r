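# Reference disk-diffusion activity grid for the Streptomyces strain against
# Bacillus subtilis: "+" = inhibition zone wider than the 6 mm disk,
# "-" = no zone. Same design vocabulary as the DPPH grid.
condition,fraction,w1,w3,w5,w7,w9,w11
O2,cultural_liquid,-,-,+,+,+,+
O3,cultural_liquid,-,-,+,+,+,+
C,cultural_liquid,+,-,-,-,-,-
O2,biomass,-,-,-,-,-,-
O3,biomass,-,-,-,-,-,+
C,biomass,-,-,-,-,-,-
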