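>RNY5_83mer
AGUUGGUCCGAGUGUUGUGGGUUAUUGUUAAGUUGAUUUAACAUUGUCUCCCCCCACAACCGCGCUUGACUAGCUUGCUGUUU
>RNY5_31mer
AGUUGGUCCGAGUGUUGUGGGUUAUUGUUAA
>RNY5_23mer
AGUUGGUCCGAGUGUUGUGGGUU
>RNY5_31mer_scrambled
UGGUGCGUGUUGUUUAGAUUAAGUGGUUGAC
>RNY5_motif_deleted
AGUUGGUCCGAGUUUAUUGUUAA
>RNY5_motif_scrambled
AGUUGGUCCGAGUACGUACAGUUAUUGUUAA
>RNY5_3p_32mer
CCCCACAACCGCGCUUGACUAGCUUGCUGUUU
>RNY5_ds_sense_32mer
AGUUGGUCCGAGUGUUGUGGGUUAUUGUUAAG
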