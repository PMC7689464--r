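# Default contaminant blocklist, matched on UniProt accession.
# One accession per line; '#' starts a comment. Edit freely.
# Human keratins
P04264  # KRT1
P35908  # KRT2
P35527  # KRT9
P13645  # KRT10
P02533  # KRT14
P02538  # KRT6A
P04259  # KRT6B
P08779  # KRT16
P19013  # KRT4
P13647  # KRT5
P08729  # KRT7
P05787  # KRT8
P05783  # KRT18
P08727  # KRT19
# Serum albumin (human, bovine)
P02768  # ALB
P02769  # ALB (Bos taurus)
# Trypsin (porcine, bovine; digestion enzyme)
P00761  # TRYP_PIG
P00760  # TRY1_BOVIN
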