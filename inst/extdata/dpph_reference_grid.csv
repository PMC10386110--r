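# Reference DPPH (radical-scavenging) activity grid for the Streptomyces
# strain: "+" = antioxidant activity detected, "-" = not detected.
# Conditions: C natural aeration, O2 elevated oxygen, O3 elevated oxygen +
# ozone; weeks 1,3,5,7,9,11; fractions cultural_liquid and biomass.
condition,fraction,w1,w3,w5,w7,w9,w11
O2,cultural_liquid,+,+,+,+,+,+
O3,cultural_liquid,+,+,-,+,+,+
C,cultural_liquid,-,+,-,-,-,-
O2,biomass,+,+,+,+,+,+
O3,biomass,+,+,-,+,+,+
C,biomass,-,+,-,-,-,-
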