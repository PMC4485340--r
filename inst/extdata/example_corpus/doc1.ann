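T1	Software 7 12	BLAST
T2	Database 25 32	UniProt
T3	Database 46 59	Gene Ontology
T4	Software 92 104	Bioconductor
T5	Software 106 111	BLAST
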