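location	contrast	peak_x	peak_y	peak_z	extent	t_value	df	cohens_d	n1	n2
right_postcentral_precentral	two_sample	51	-18	42	253	-3.39	106	-0.65	54	54
left_postcentral_precentral	two_sample	-57	-6	48	220	-3.39	106	-0.65	54	54
right_fusiform_cerebellum6	two_sample	18	-45	-12	121	-3.39	106	-0.65	54	54
left_superior_middle_frontal	two_sample	-27	45	21	88	4.43	106	0.85	54	54
left_fusiform_cerebellum6	two_sample	-30	-48	-24	85	-3.40	106	-0.65	54	54
right_calcarine_lingual	two_sample	27	-57	9	58	-3.42	106	-0.66	54	54
right_postcentral	two_sample	63	-6	33	53	-3.40	106	-0.65	54	54
left_superior_parietal	two_sample	-15	-57	66	44	-3.41	106	-0.66	54	54
left_middle_inferior_frontal_triangular	two_sample	-30	15	33	38	4.94	106	0.95	54	54
left_fusiform_posttreatment	paired	-30	-45	-9	41	4.57	35	1.08	36	NA
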