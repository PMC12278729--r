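sample_id	contig	start	end	svtype	genotype_state	mean_log2_ratio	n_bins	n_internal_het_snvs	discordant_pair_support	clipped_read_support
S1	chr2	55556194	55565990	DEL	heterozygous	-0.95	10	0	TRUE	TRUE
S2	chr2	55556194	55565990	DEL	heterozygous	-0.92	10	0	TRUE	TRUE
S1	chr1	108733326	108737251	DEL	heterozygous	-1.05	4	0	TRUE	FALSE
S2	chr1	108733326	108737251	DEL	heterozygous	-1.01	4	0	TRUE	FALSE
S1	chr5	40000001	40012000	DEL	heterozygous	-0.90	12	6	FALSE	FALSE
S2	chr5	40001001	40013000	DEL	heterozygous	-0.88	12	6	FALSE	FALSE
S1	chr7	86000001	86008000	DEL	heterozygous	-1.10	8	4	FALSE	FALSE
S2	chr7	86000001	86008000	DEL	heterozygous	-1.07	8	4	FALSE	FALSE
S1	chr11	3000001	3009000	DEL	heterozygous	-0.85	9	5	FALSE	FALSE
S2	chr11	3000001	3009000	DEL	heterozygous	-0.83	9	5	FALSE	FALSE
S1	chr9	120000001	120010000	DEL	heterozygous	-1.00	10	0	FALSE	FALSE
S1	chr16	21500001	21510000	DEL	heterozygous	-0.90	10	1	TRUE	FALSE
S2	chr16	21500001	21510000	DEL	heterozygous	-0.93	10	1	TRUE	FALSE
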