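gene	protein_length	n_prioritized	variant_density	mean_ddg	mean_cadd
ATP6V1B1	513	17	33.1	2.8	27.8
CDC14A	623	23	36.9	2.7	28.3
CLRN1	232	10	43.1	2.3	26.6
DCAF17	520	22	42.3	3.2	27.9
DIABLO	239	14	58.6	2.7	28.4
ELMOD3	381	12	31.5	3.1	27.6
GIPC3	312	13	41.7	3.1	27.5
GJB2	226	10	44.2	3.1	27.6
GJB3	270	11	40.7	3.4	27.3
GRXCR1	290	10	34.5	2.8	27.6
GSDME	496	19	38.3	3.4	27.4
HARS2	512	17	33.2	2.7	28.8
KARS1	625	19	30.4	2.7	28.3
LHFPL5	219	7	32.0	3.3	28.4
LOXL3	753	27	35.9	3.0	27.8
MANBA	879	27	30.7	3.1	27.7
MASP1	728	37	50.8	3.1	28.6
MSRB3	185	7	37.8	3.4	28.3
MYO3A	1616	62	38.4	3.0	28.4
MYO6	1294	40	30.9	3.1	27.9
MYO7A	2215	87	39.3	3.0	28.0
NARS2	477	22	46.1	2.8	28.3
OTOF	1997	60	30.0	3.2	28.4
OTOGL	2344	143	61.0	3.1	28.2
PCDH15	1790	55	30.7	3.1	27.9
POLR1C	346	16	46.2	2.9	27.9
RDX	604	24	39.7	3.0	27.5
SEMA3E	775	24	31.0	3.3	28.1
SLC17A8	589	18	30.6	2.8	28.9
SLC19A2	497	35	70.4	3.5	28.1
SLC22A4	551	21	38.1	3.0	28.3
SLC26A4	780	45	57.7	2.9	28.1
SLC44A4	710	39	54.9	3.0	28.5
SLC52A2	445	16	36.0	3.2	26.9
SLC52A3	469	16	34.1	3.2	27.3
TECTA	2155	84	39.0	3.1	28.0
TMC1	760	24	31.6	3.3	29.0
TSPEAR	601	19	31.6	3.5	28.1
WFS1	890	46	51.7	3.0	27.7
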