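# tagged tight-binding results
fermi_level = -4.20 eV
band_energy = -14.30 eV
n_electrons = 4
e_h0 = -20.50 eV
e_scc = -0.45 eV
e_3rd = -0.03 eV
e_rep = 0.80 eV
e_mbd = -0.15 eV
dipole = 0.1 0.0 0.0 eA
eigenvalues = -9.50 -6.20 -1.10 0.70 eV
occupations = 2 2 0 0
mulliken = 0.12 -0.12
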