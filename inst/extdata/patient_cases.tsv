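patient_id	gene	inheritance	priority_variant	second_variant	second_classification	segregation
1	CDH23	AR	NP_071407.4:p.Tyr2883Ser	Arg2795Ter	P	NA
2	GRXCR1	AR	NP_001073945.1:p.Tyr142Cys	Gln283Ter	P	Yes
3	HARS2	AR	NP_036340.1:p.Tyr364Cys	Arg150Cys	LP	Yes
4	MYO6	AD	NP_001355794.1:p.Cys1236Arg	None	NA	NA
5	PDZD7	AR	NP_001182192.1:p.Ile269Ser	Arg56ProfsTer24	P	NA
6	TMPRSS3	AR	NP_076927.1:p.Met384Lys	His70ThrfsTer19	P	Yes
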