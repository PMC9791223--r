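variable	level	group	count
enrollment	excluded	all	55
enrollment	included	all	2063
sex	men	mets_negative	532
sex	women	mets_negative	759
sex	men	mets_positive	399
sex	women	mets_positive	373
age	under_50	mets_negative	475
age	50_to_65	mets_negative	546
age	over_65	mets_negative	270
age	under_50	mets_positive	218
age	50_to_65	mets_positive	348
age	over_65	mets_positive	206
race	white	mets_negative	994
race	african_american	mets_negative	207
race	native_american	mets_negative	79
race	asian	mets_negative	9
race	other	mets_negative	2
race	white	mets_positive	549
race	african_american	mets_positive	158
race	native_american	mets_positive	57
race	asian	mets_positive	5
race	other	mets_positive	3
education	hs_or_less	mets_negative	265
education	some_college	mets_negative	692
education	postgraduate	mets_negative	334
education	hs_or_less	mets_positive	222
education	some_college	mets_positive	385
education	postgraduate	mets_positive	165
nutritional_status	underweight	mets_negative	11
nutritional_status	normal_weight	mets_negative	490
nutritional_status	overweight	mets_negative	328
nutritional_status	obese	mets_negative	462
nutritional_status	underweight	mets_positive	0
nutritional_status	normal_weight	mets_positive	32
nutritional_status	overweight	mets_positive	192
nutritional_status	obese	mets_positive	548
regular_exercise	no	mets_negative	254
regular_exercise	yes	mets_negative	1037
regular_exercise	no	mets_positive	253
regular_exercise	yes	mets_positive	519
smoking	never	mets_negative	753
smoking	former	mets_negative	375
smoking	current	mets_negative	161
smoking	never	mets_positive	411
smoking	former	mets_positive	252
smoking	current	mets_positive	108
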