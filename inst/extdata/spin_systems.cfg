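# Example spin-system configuration: the S = 1/2 species of a
# menaquinone-linked formate dehydrogenase. g-values and the proton
# hyperfine tensor are published spin-Hamiltonian parameters;
# linewidths are synthetic placeholders (see exampleSpinSystems()).

[system MoV]
g = 1.9971 1.9933 1.9890
linewidth_mode = H_strain
linewidth = 0.30 0.30 0.30
hyperfine = 13 13 11 spin=0.5 n=1
weight = 1

[system MSK]
g = 2.0054 2.0051 2.0023
linewidth_mode = H_strain
linewidth = 0.9712 0.9712 0.9712
weight = 1

[system Fe2S2]
g = 2.020 2.020 1.939
linewidth_mode = g_strain
linewidth = 0.008 0.008 0.010
weight = 1

[system Fe4S4slow1]
g = 2.047 1.948 1.897
linewidth_mode = g_strain
linewidth = 0.015 0.015 0.018
weight = 1
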