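>Bri2_22 wild-type Bri2 peptide, first 22 residues (extension point after C22)
EASNCFAIRHFENKFAVETLIC
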