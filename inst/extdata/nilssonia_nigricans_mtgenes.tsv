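name	category	strand	start	end	start2	end2	anticodon	start_codon	stop_codon
trnF	tRNA	H	59	128			GAA
rrnS	rRNA	H	129	1110
trnV	tRNA	H	1109	1178			TAC
rrnL	rRNA	H	1179	2789
trnL2	tRNA	H	2790	2865			TAA
nad1	PCG	H	2879	3823				ATA	A
trnI	tRNA	H	3832	3901			GAT
trnQ	tRNA	L	3901	3971			TTG
trnM	tRNA	H	3971	4039			CAT
nad2	PCG	H	4040	5068				ATG	A
trnW	tRNA	H	5082	5156			TCA
trnA	tRNA	L	5161	5229			TGC
trnN	tRNA	L	5231	5304			GTT
trnC	tRNA	L	5338	5403			GCA
trnY	tRNA	L	5404	5471			GTA
cox1	PCG	H	5476	7008				ATT	A
trnS2	tRNA	L	7013	7083			TGA
trnD	tRNA	H	7084	7152			GTC
cox2	PCG	H	7153	7833				ATG	T
trnK	tRNA	H	7841	7916			TTT
atp8	PCG	H	7918	8076				ATG	A
atp6	PCG	H	8073	8753				ATG	TAA
cox3	PCG	H	8756	9538				ATG	T
trnG	tRNA	H	9540	9609			TCC
nad3	PCG	H	9610	9958				ATG	AGA
trnR	tRNA	H	9960	10030			TCG
nad4l	PCG	H	10032	10325				ATG	TAA
nad4	PCG	H	10322	11692				ATG	C
trnH	tRNA	H	11703	11772			GTG
trnS1	tRNA	H	11773	11834			GCT
trnL1	tRNA	H	11834	11905			TAG
nad5	PCG	H	11906	13681				ATG	TAA
nad6	PCG	L	13683	14204				ATG	T
trnE	tRNA	L	14205	14272			TTC
cytb	PCG	H	14282	15409				ATC	A
trnT	tRNA	H	15419	15492			TGT
trnP	tRNA	L	15495	15564			TGG
CR	CR	H	15565	16796	1	58
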