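chr1	108733325	108737251	DEL_chr1_common	0.2357
chr3	50000000	50050000	DEL_chr3_common	0.1500
chr2	55300000	55340000	DUP_chr2_rare	0.0002
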