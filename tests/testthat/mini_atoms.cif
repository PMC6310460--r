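data_mini
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_seq_id
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.pdbx_PDB_model_num
ATOM   1 N  N    . LYS A 25 0.000  0.000 0.000 1.00 1
ATOM   2 C  CA   . LYS A 25 1.458  0.000 0.000 1.00 1
ATOM   3 C  CB   A LYS A 25 2.000  1.400 0.000 0.40 1
ATOM   4 C  CB   B LYS A 25 2.100  1.300 0.200 0.60 1
ATOM   5 N  NZ   . LYS A 25 3.500  3.500 1.000 1.00 1
HETATM 6 P  PA   . ATP A 1  5.000  5.000 5.000 1.00 1
HETATM 7 O  "O5'" . ATP A 1 4.000 4.400 5.700 1.00 1
HETATM 8 MG MG   . MG  A 2  6.500  6.500 6.500 1.00 1
#
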