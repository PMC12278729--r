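chr2	55514448	55647905	CCDC88A
chr1	108700000	108738000	SLC25A24
chr5	39990000	40020000	PANEL_G003
chr7	85990000	86010000	PANEL_G004
chr11	2990000	3010000	PANEL_G005
chr9	119990000	120020000	PANEL_G006
chr16	21490000	21520000	PANEL_G007
chr4	1500000	1600000	PANEL_G008
chr17	2800000	2900000	PANEL_G009
chr19	50200000	50300000	PANEL_G010
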