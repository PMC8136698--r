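# 3-spectrum of the two example reads
AAT
ATA
ATT
TAA
TAT
TTA
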