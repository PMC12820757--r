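# Fixture formats

Small plain-text examples of the two tight-binding results dialects accepted
by `parse_tb_results()`. These files are normative: the parser is tested
byte-for-byte against them.

## `tb_detailed_example.txt` — "detailed" dialect

Free-text blocks in the style of verbose tight-binding program output.
Recognised content, one item per labelled line:

- `Fermi level: <x> <unit>` — unit `eV` or `H`/`Ha`/`Hartree`
  (Hartree values are multiplied by 27.211386245988).
- `Band energy:`, `Number of electrons:`, `Energy H0:`, `Energy SCC:`,
  `Third order energy:`, `Repulsive energy:`, `MBD energy:` — same
  number-plus-unit layout.
- `Dipole moment: <x> <y> <z> <unit>` — unit `eA` (e*Angstrom) or `au`
  (e*Bohr, multiplied by 0.529177210903).
- `Eigenvalues /eV:` (or `/H`) followed by one `energy occupation` pair per
  line; the occupation column marks the occupied/virtual split.
- `Mulliken charges:` followed by one net atomic charge per line (the last
  number on each line is taken, so `index symbol charge` layouts also work).
- optional `Net charge: <q>` for ions.

## `tb_tagged_example.txt` — "tagged" dialect

One `key = values [unit]` pair per line; `#` starts a comment. Keys:
`fermi_level`, `band_energy`, `n_electrons`, `e_h0`, `e_scc`, `e_3rd`,
`e_rep`, `e_mbd`, `dipole` (3 values), `eigenvalues` (ascending),
`occupations`, `mulliken`, and optionally `charge` and `gap` (the stated gap
is cross-checked against the eigenvalues to 1e-6 eV). Units as above.
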