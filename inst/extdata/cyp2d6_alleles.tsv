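gene	allele	suballele	function	activity_score	structural	variants
CYP2D6	*1	.	normal	1	none	.
CYP2D6	*1	*1.069	normal	1	none	5243:C>T:rs1208092320:.:42130568
CYP2D6	*1	*1.070	normal	1	none	4674:T>C:.:.:42131137
CYP2D6	*1	*1.071	normal	1	none	7032:G>A:rs752453767:.:42128779
CYP2D6	*2	.	normal	1	none	7870:C>T:rs16947:R296C:42127941;9200:C>G:rs1135840:S486T:42126611
CYP2D6	*2	*2.038	normal	1	none	7265:C>T:rs936306239:.:42128546
CYP2D6	*2	*2.039	normal	1	none	6810:A>G:rs76326664:.:42129001
CYP2D6	*4	.	no_function	0	none	5119:C>T:rs1065852:P34S:42130692;6866:G>A:rs3892097:.:42128945
CYP2D6	*4	*4.036	no_function	0	none	5102:G>A:rs377617003:R28H:42130709
CYP2D6	*4	*4.037	no_function	0	none	8428:T>C:rs28371728:.:42127383
CYP2D6	*4	*4.038	no_function	0	none	8446:C>G:rs1483955943:.:42127365
CYP2D6	*5	.	no_function	0	deletion	.
CYP2D6	*6	.	no_function	0	none	7569:CT>C:rs5030655:.:42128242
CYP2D6	*9	.	decreased	0.5	none	7635:AAAG>A:rs5030656:K281del:42128176
CYP2D6	*10	.	decreased	0.25	none	5119:C>T:rs1065852:P34S:42130692
CYP2D6	*33	.	normal	1	none	7722:A>C:rs28371717:A237S:42128089
CYP2D6	*35	.	normal	1	none	5036:G>A:rs769258:V11M:42130775;7870:C>T:rs16947:R296C:42127941;9200:C>G:rs1135840:S486T:42126611
CYP2D6	*41	.	decreased	0.5	none	8008:G>A:rs28371725:.:42127803;7870:C>T:rs16947:R296C:42127941;9200:C>G:rs1135840:S486T:42126611
CYP2D6	*59	.	decreased	0.5	none	2500:G>C:rs1080985:.:42133311;7870:C>T:rs16947:R296C:42127941;9200:C>G:rs1135840:S486T:42126611
CYP2D6	*71	.	uncertain	.	none	5144:G>A:rs118203758:G42E:42130667
CYP2D6	*108	.	unknown	.	none	8301:A>G:rs202102799:Y355C:42127510
CYP2D6	*186	.	unknown	.	none	6706:G>T:rs1399114415:G145C:42129105
CYP2D6	*186	*186.001	unknown	.	none	.
CYP2D6	*41	*41.010	decreased	0.5	none	7373:G>A:rs79650744:.:42128438
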