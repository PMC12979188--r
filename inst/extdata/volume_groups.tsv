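parameter	value	description
ch2_increment	26.9	volume per chain carbon (CH2), A^3
chain_terminal	27.0	extra volume for the terminal methyl of each chain, A^3
double_bond_decrement	20.4	volume removed per C=C double bond, A^3
ether_delta	10.0	volume adjustment for an ether (alkyl/alkenyl) linkage, A^3 per molecule
sphingoid_t_extra	11.0	extra hydroxyl volume for phytosphingoid (t) backbones, A^3
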