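chr16	21500000	21507200	segdup_chr16_a
chr5	40000000	40001000	segdup_chr5_a
chr12	6000000	6040000	segdup_chr12_a
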