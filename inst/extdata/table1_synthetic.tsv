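sample	C_host_mM	C_ligand_mM	D_ligand_free	D_host_free	D_obs_ligand	D_obs_host
1+2_synthetic	1.5	4.5	3.07	1.13	2.470684	1.13
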