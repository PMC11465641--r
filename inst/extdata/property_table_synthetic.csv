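compound_id,log_kow_experimental,log_kow_estimated,molecular_weight,complexity,heavy_atom_count,h_bond_donors,h_bond_acceptors,tpsa,formal_charge,rotatable_bonds
PCB28,5.67,5.66,257.5,236,15,0,0,0,0,1
PCB52,5.84,5.91,292.0,266,16,0,0,0,0,1
PCB101,6.38,6.33,326.4,296,17,0,0,0,0,1
PCB118,6.74,6.57,326.4,296,17,0,0,0,0,1
PCB138,6.83,6.73,360.9,321,18,0,0,0,0,1
PCB153,6.92,6.80,360.9,321,18,0,0,0,0,1
PCB180,7.36,7.21,395.3,347,19,0,0,0,0,1
DDEPP,6.51,6.00,318.0,318,20,0,0,0,0,2
DDTPP,6.91,6.79,354.5,296,21,0,0,0,0,3
HCB,5.73,5.86,284.8,134,12,0,0,0,0,0
BDE47,6.81,6.77,485.8,263,21,0,1,9.2,0,2
PFOS,,4.49,500.1,468,26,1,9,63,0,8
CP_C12H20Cl6,,,359.0,188,18,0,0,0,0,9
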