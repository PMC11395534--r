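# Per-element atomic properties used by the descriptor stack.
# weight: conventional IUPAC standard atomic weights (g/mol), the table used by
#         elemental-analysis software (pre-2021 abridgement values).
# sanderson_en: Sanderson electronegativity (Sanderson 1983 scale).
# polarizability: static atomic polarizability (cubic Angstrom, CRC values).
# pqn: principal quantum number of the valence shell.
# valence_electrons: number of valence-shell electrons.
element,weight,sanderson_en,polarizability,pqn,valence_electrons
H,1.00794,2.592,0.667,1,1
C,12.0107,2.746,1.76,2,4
N,14.0067,3.194,1.10,2,5
O,15.9994,3.654,0.802,2,6
F,18.9984032,4.000,0.557,2,7
P,30.973762,2.515,3.63,3,5
S,32.065,2.957,2.90,3,6
Cl,35.453,3.475,2.18,3,7
Br,79.904,3.219,3.05,4,7
I,126.90447,2.778,5.35,5,7
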