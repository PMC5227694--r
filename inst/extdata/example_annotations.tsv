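# Synthetic annotation table for the worked example: term -> accession
# mappings in the GAF-like layout the enrichment stage reads.
accession	term_id	term_label
SYN0001	T:0001	cytoplasmic granule assembly
SYN0002	T:0001	cytoplasmic granule assembly
SYN0003	T:0002	translation regulation
SYN0004	T:0002	translation regulation
SYN0005	T:0002	translation regulation
SYN0001	T:0003	stress response
SYN0003	T:0003	stress response
SYN0006	T:0003	stress response
SYN0007	T:0004	metabolic process
SYN0008	T:0004	metabolic process
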