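# Unstable / implausible ion substructures, one "name SMARTS" per line.
# Version: ilgen-1. Lines starting with '#' are comments.
# Bare carbanion with no adjacent stabilizing group (carbonyl, nitrile,
# sulfonyl, aromatic ring, adjacent onium centre).
carbanion [#6-;!$([#6-]C=[OX1]);!$([#6-]C#N);!$([#6-][SX4](=O)=O);!$([#6-]a);!$([#6-]~[N+,P+,S+])]
# Alkoxide on sp3 carbon without an alpha electron-withdrawing group.
alkoxide [OX1-][CX4;!$([CX4]C=[OX1]);!$([CX4]C#N);!$([CX4][SX4](=O)=O);!$([CX4]C(F)(F)F)]
# N-acylated quaternary ammonium ("quaternary amide") centre.
quaternary_amide [NX4+][CX3]=[OX1]
# Aromatic N-acyl azolium (acyl on positively charged aromatic nitrogen).
aromatic_n_acyl [n+][CX3]=[OX1]
# Directly bonded opposite formal charges, excluding the legitimate
# nitro / N-oxide / azide-type ylides.
adjacent_opposite_charges [O-;!$([O-][N+,n+]);!$([O-][S+,P+])]~[*+]
adjacent_opposite_charges_n [N-;!$([N-][N+]=[N,O]);!$([N-]=[N+])]~[*+]
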