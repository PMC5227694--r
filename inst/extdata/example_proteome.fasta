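>SYN0001
VYPLGQYPPRSIKCKKLTARHDPGIGETLMALQRYICDFGRVERIDEQNVATVTEKTQLDSSLLNSSYVNEWPGGYTAGK
LISEPIGGDTHAGWESPKVVAQLACDGGVASPDDVVNPRC
>SYN0002
AEQNGQRAMTSESIFHKRDHGKQSNSQGNVLPSYRKLYKQSCVKPHLVYNMRHLLRTKPIFPGMFYPPVACLGSLQGLVL
RDVERIGASDTIQTIQDAPILQPKTMKMFMFPYLATSELC
>SYN0003
RSEDPSYVAKAGEVRLTETPHGSTKSDAAMHCGLGGVDKSSYGVPRSVSVLNVPQDVRGDGGMGRVLLYVAQMVNDRKQS
ARSGVNITQLYASISDVCCGDCQSVKLELLLDEQIGHRPY
>SYN0004
HKAPPTSQKMMDTISFFNMKQRVLLGRLHYFDTRHYPSTYLTAAGMADVNLMGQATQFSWVGFSIYGREPPALDSLSIDM
TLDAFLPSVVSSFSGTWQSQSAKCHQANAAAPGIQIQPLK
>SYN0005
RASDSLLRALKPSERKSPEKGRGMFGQEILSLRTKQANNAEKGQSPCVGPARFPRTNVIRIEWEKAFFLVADIVPRVDLC
SLQGEHSKSEPEGFTALSTHNCCIPEYEGFATGNNEPLAN
>SYN0006
ALRDGGLENWFFYYRWPPRQVTLDSGRSLTLSLMPPASISKDIRIKSELEQHMVKSAKYAPEKCETTPQHLERNKPLGMT
IDKSQEPPKTHPLMTEFISAQPVNVNDNMFLDLESPADVR
>SYN0007
LSIKTYGSFGMYLPKSDFGDCYSQYLETGANDCAVRVPASAARGDFKLVCCTDDCLLMSIPSTHLCQPEKDKAENFQVVV
ESYGKDFQINVNTYSPATVLKVWRQIPPRKDGVRTDLASP
>SYN0008
KTGPKCYWDGAEPQEAFLIKDTDGCIQKIGRSSAWFVAVQPTPFNEDDEINGQYPTNEVATERNSPGDERLRVSGHSQIN
PSDEWPHARARYRRGEWCPSEHFDAVTSIFVQNLETPEVS
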