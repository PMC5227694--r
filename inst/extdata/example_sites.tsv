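accession	position	residue	kind	oxidized_fraction
SYN0001	61	S	phospho	NA
SYN0001	83	S	phospho	NA
SYN0001	90	T	phospho	NA
SYN0001	96	S	phospho	NA
SYN0001	98	K	ubiquityl	NA
SYN0003	2	S	phospho	NA
SYN0003	41	S	phospho	NA
SYN0004	36	Y	phospho	NA
SYN0004	75	S	phospho	NA
SYN0004	80	M	sulfoxide	0.48674775511026386
SYN0004	2	K	ubiquityl	NA
SYN0005	45	S	phospho	NA
SYN0005	107	Y	phospho	NA
SYN0005	35	K	ubiquityl	NA
SYN0005	35	K	acetyl	NA
SYN0006	79	M	sulfoxide	0.3341248081997037
SYN0006	89	K	ubiquityl	NA
SYN0007	8	S	phospho	NA
SYN0007	28	T	phospho	NA
SYN0007	72	K	acetyl	NA
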