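DIP
IPA
MAS
ACT
BBB
CMAP
VOC
DNA
RNA
PCR
BMI
CNS
EEG
MRI
ATP
GDP
HIV
SNP
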