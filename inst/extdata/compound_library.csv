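# Open reference library of actinobacterial natural products used for
# accurate-mass dereplication. Stands in for a commercial natural-product
# dictionary: it is NOT exhaustive, only a curated fixture.
# Records with a trustworthy molecular formula leave monoisotopic_mass empty
# (it is computed from the formula at load time); records without one carry a
# stored literature mass. Rows named decoy_* are SYNTHETIC mass decoys added
# so that range queries and source filters have non-trivial negatives.
# activities is a semicolon-separated annotation set (may be empty).
name,formula,monoisotopic_mass,biological_source,activities
desferrioxamine E,C27H48N6O9,,Streptomyces,antioxidant;siderophore;antibiotic
ferrioxamine A2,,599.2496,Streptomyces,siderophore
streptomyceamide B,,264.0747,Streptomyces,
arginomycin,,436.2219,Streptomyces,antibiotic
nivelactam,,439.2704,Streptomyces,
antimycin A,,440.3655,Streptomyces,antibiotic;antifungal
"5,10,11-trihydroxy-3-cadinanone",C15H26O4,,Streptomyces,
11-methyl-2-tridecanone,C14H28O,,Streptomyces,
10-methylhexadecanoic acid,C17H34O2,,Streptomyces,
octahydro-7a-methyl-1-(1-methyl-2-oxopropyl)-5-oxo-1H-indene-4-propanoic acid,,294.181,Rhodococcus,antifungal
decoy_01,,181.0739,Streptomyces,
decoy_02,,212.6840,Rhodococcus,
decoy_03,,234.1620,Streptomyces,antibiotic
decoy_04,,265.1201,Nocardia,
decoy_05,,302.3028,Streptomyces,
decoy_06,,315.1107,Rhodococcus,antifungal
decoy_07,,350.1264,Streptomyces,antioxidant
decoy_08,,398.2210,Micromonospora,
decoy_09,,436.4100,Streptomyces,
decoy_10,,455.2900,Rhodococcus,
decoy_11,,470.3200,Streptomyces,antibiotic
decoy_12,,512.2531,Streptomyces,
decoy_13,,530.1990,Nocardia,siderophore
decoy_14,,577.4000,Streptomyces,
decoy_15,,611.2745,Rhodococcus,
decoy_16,,640.3100,Streptomyces,antifungal
decoy_17,,666.4320,Streptomyces,
decoy_18,,699.4000,Micromonospora,
decoy_19,,723.2200,Streptomyces,antioxidant
decoy_20,,760.5000,Rhodococcus,
decoy_21,,812.4500,Streptomyces,
decoy_22,,850.5500,Streptomyces,antibiotic
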