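# Monoisotopic atomic masses (Da) of the most abundant isotope of each element.
# Values follow IUPAC/CODATA tabulations to >= 8 decimals (12C is exactly 12).
# Editable resource: rows may be added for additional elements.
symbol,monoisotopic_mass
H,1.00782503207
C,12.0
N,14.0030740052
O,15.9949146221
F,18.99840322
Na,22.98976928
Mg,23.985041697
Si,27.97692653465
P,30.97376163
S,31.97207100
Cl,34.96885268
K,38.96370668
Ca,39.962590863
Fe,55.93493633
Zn,63.92914201
Se,79.9165218
Br,78.9183376
I,126.9044719
B,11.0093054
Cu,62.92959772
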