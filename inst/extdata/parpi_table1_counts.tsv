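section	category	n
totals	parpi_reports	24045
totals	hematotoxicity_reports	4088
totals	corpus_reports	9264231
gender	Female	3367
gender	Male	155
gender	Unknown or missing	566
age	<18	6
age	18-65	1195
age	>65	1066
age	Unknown or missing	1821
drug	olaparib	1350
drug	niraparib	1821
drug	rucaparib	766
drug	talazoparib	151
onset	0-30	934
onset	31-60	206
onset	61-90	176
onset	91-180	175
onset	181-360	128
onset	>=361	188
onset	Unknown or missing	2281
indication	Ovarian cancer	2779
indication	Breast cancer	189
indication	Others	786
indication	Unknown or missing	334
serious_outcome	Death	358
serious_outcome	Life-threatening	414
serious_outcome	Hospitalization	1178
serious_outcome	Disability	35
serious_outcome	Others	2751
country	US	2647
country	JP	402
country	FR	216
country	IT	103
country	DE	92
reporter	Physician	1175
reporter	Pharmacist	111
reporter	Other health-professional	723
reporter	Consumer	1664
reporter	Unknown	415
year	2021	871
year	2020	1013
year	2019	836
year	2018	836
year	2017	364
year	2016	111
year	2015	57
deaths_by_drug	olaparib	220
deaths_by_drug	niraparib	85
deaths_by_drug	rucaparib	29
deaths_by_drug	talazoparib	24
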