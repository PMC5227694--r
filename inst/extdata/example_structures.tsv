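accession	pdb_path	dssp_path	chain	offset
SYN0001	SYN0001.pdb	SYN0001.dssp	A	0
SYN0002	SYN0002.pdb	SYN0002.dssp	A	0
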