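chr2	55549999	55550200	CCDC88A_13
chr2	55556999	55557150	CCDC88A_14
chr2	55559999	55560180	CCDC88A_15
chr2	55564999	55565200	CCDC88A_16
chr2	55566999	55567100	CCDC88A_17
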