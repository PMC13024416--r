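species	subfamily	numt_count	numt_total_length	numt_pct_of_genome
Acleris cristana	Tortricinae	34	13146	0.00234
Acleris emargana	Tortricinae	9	1500	0.00022
Acleris holmiana	Tortricinae	19	3632	0.00056
Acleris literana	Tortricinae	33	7563	0.00112
Acleris sparsana	Tortricinae	15	6386	0.00108
Apotomis betuletana	Olethreutinae	66	18523	0.00271
Apotomis capreana	Olethreutinae	66	14391	0.00194
Apotomis turbidana	Olethreutinae	50	8761	0.00122
Archips crataeganus	Olethreutinae	29	6899	0.00110
Archips xylosteana	Tortricinae	64	26076	0.00401
Choristoneura fumiferana	Tortricinae	46	4157	0.00072
Cydia amplana	Tortricinae	18	2246	0.00045
Cydia splendana	Olethreutinae	22	3612	0.00057
Cydia strobilella	Olethreutinae	121	38506	0.00710
Epinotia bilunana	Olethreutinae	153	33531	0.00509
Epinotia demarniana	Olethreutinae	172	70532	0.00959
Epinotia nisella	Olethreutinae	88	12819	0.00219
Epinotia ramella	Olethreutinae	89	22787	0.00291
Eudemis profundana	Olethreutinae	55	9557	0.00138
Grapholita molesta	Olethreutinae	15	4261	0.00082
Hedya salicella	Olethreutinae	207	76799	0.01035
Leguminivora glycinivorella	Olethreutinae	32	5993	0.00090
Notocelia uddmanniana	Olethreutinae	94	23444	0.00295
Pammene aurita	Olethreutinae	208	76405	0.00733
Pammene fasciana	Olethreutinae	13	2068	0.00037
Pandemis cinnamomeana	Tortricinae	29	14033	0.00329
Tortricodes alternella	Tortricinae	9	1808	0.00041
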