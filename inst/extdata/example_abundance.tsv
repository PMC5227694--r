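accession	abundance
SYN0001	32772.82247120931
SYN0002	826.0962123577752
SYN0003	13632.987203502329
SYN0004	8144.334365526763
SYN0005	2136.082632257066
SYN0006	30.356031413515584
SYN0007	1824.6844844724462
SYN0008	947.3975408366651
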