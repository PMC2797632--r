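# Synthetic reconstruction of the nearly-ubiquitous bacterial tRNA
# anticodon set (ubi-tRNAs): tRNA species present in virtually all
# bacterial genomes, whose Watson-Crick codon partners are the generally
# preferred codons. Built from wobble-pairing reasoning, NOT a copy of any
# published table; replace with your own list to reproduce a specific one.
# Anticodons 5'->3', DNA alphabet.
amino_acid	anticodon
Ala	TGC
Arg	ACG
Arg	TCT
Asn	GTT
Asp	GTC
Cys	GCA
Gln	TTG
Glu	TTC
Gly	GCC
Gly	TCC
His	GTG
Ile	GAT
Leu	TAG
Leu	TAA
Lys	TTT
Met	CAT
Phe	GAA
Pro	TGG
Ser	GCT
Ser	TGA
Thr	TGT
Trp	CCA
Tyr	GTA
Val	TAC
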