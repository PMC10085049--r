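# Previously reported high-confidence CNVR in the Dairy Gir cattle genome:
# the 15 of 48 unique regions whose coordinates are published in the main
# text (ARS-UCD1.2 assembly, 1-based inclusive). Types as reported.
cnvr_id	chrom	start	end	cnvr_type
CNVR3	2	719378	745361	DUPLICATION
CNVR8	3	54329751	54851188	COMPLEX
CNVR10	4	105218001	105292500	DUPLICATION
CNVR14	7	9455783	9693750	DELETION
CNVR16	7	10055082	10135500	DELETION
CNVR17	7	41582849	41938000	DELETION
CNVR18	9	5051796	5177690	DELETION
CNVR19	9	15095199	15271750	DUPLICATION
CNVR32	13	534618	53511604	DELETION
CNVR34	15	44870278	44942116	DELETION
CNVR37	18	13328574	13397500	DUPLICATION
CNVR40	19	23956716	23987626	COMPLEX
CNVR41	20	3549957	3609244	DELETION
CNVR44	23	25679501	25705975	DELETION
CNVR46	28	123251	413750	DELETION
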