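group
amino acid biosynthesis
protein folding and stability
replication and repair
transcription
translation
ribosome-related
RNA-related
aminoacyl tRNA synthetases
ribosomal subunit protein
TCA cycle
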