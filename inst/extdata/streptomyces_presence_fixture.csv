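# Presence/absence fixture for the Streptomyces cultivation study:
# conditions C (natural aeration), O2 (elevated oxygen), O3 (elevated oxygen
# + ozone), sampled weeks 1,3,5,7,9,11, cultural_liquid fraction.
# Each row is one LC-MS feature (neutral monoisotopic mass in Da, retention
# time in minutes); sample columns hold 1 where the feature was detected.
# Editorial rule: a cell is 1 only where the study narrative asserts a
# detection; cells the narrative is silent about (in particular control
# columns) are 0. unknown_* features are the unidentified molecules, named by
# their neutral mass. streptomyceamide B has no reported retention time
# beyond falling in the 10.6-17 min induction window; 11.0 is used here.
name,neutral_mass,rt_min,C_1,C_3,C_5,C_7,C_9,C_11,O2_1,O2_3,O2_5,O2_7,O2_9,O2_11,O3_1,O3_3,O3_5,O3_7,O3_9,O3_11
desferrioxamine E,600.3486,4.5,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
ferrioxamine A2,599.2496,2.6,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
unknown_707.5335,707.5335,6.9,0,1,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
unknown_572.3175,572.3175,4.0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
unknown_751.3685,751.3685,15.3,0,0,0,0,0,0,1,1,1,1,1,1,1,1,0,1,1,1
streptomyceamide B,264.0747,11.0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
arginomycin,436.2219,10.8,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
nivelactam,439.2704,12.1,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
antimycin A,440.3655,13.7,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
"5,10,11-trihydroxy-3-cadinanone",270.1833,12.7,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
11-methyl-2-tridecanone,212.2139,14.2,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
10-methylhexadecanoic acid,270.2561,14.3,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
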