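Fermi level: -4.20 eV
Band energy: -14.30 eV
Number of electrons: 4
Energy H0: -20.50 eV
Energy SCC: -0.45 eV
Third order energy: -0.03 eV
Repulsive energy: 0.80 eV
MBD energy: -0.15 eV
Dipole moment: 0.1 0.0 0.0 eA
Eigenvalues /eV:
 -9.50  2.0
 -6.20  2.0
 -1.10  0.0
  0.70  0.0
Mulliken charges:
  0.12
 -0.12
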