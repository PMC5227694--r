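# Illustrative Ser/Thr kinase recognition motifs in which methionine can
# act as a specificity determinant. This list is a documented EXAMPLE of
# the pattern-file format, not a curated literature compilation: lowercase
# s/t marks the phospho-acceptor, X is a wildcard, uppercase letters are
# required residues.
sM
sXXXM
sXXXMX
RXXsM
RRXsXXM
MQs
MXXsXXX
sMXE
KXXsXXXM
sXXXMD
tM
tXXXM
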