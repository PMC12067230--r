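>ADan_nt_synthetic synthetic reverse-translation of ADan (one common codon per residue; not the experimental construct)
GAAGCTTCTAATTGTTTTGCTATTAGACATTTTGAAAATAAATTTGCTGTTGAAACTTTGATTTGTTTTAATTTGTTTTTGAATTCTCAAGAAAAACATTAT
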