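>ADan 34-residue peptide (Bri2 + FDD extension)
EASNCFAIRHFENKFAVETLICFNLFLNSQEKHY
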