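cancer_type	female	male	total	stage_I	stage_II	stage_III	stage_IV
Breast	262	0	262	36	133	77	16
Endometrial	70	0	70	20	26	19	5
Cervical	137	0	137	27	58	40	12
Ovarian	155	0	155	28	64	48	15
Lung	68	158	226	40	55	80	51
AML	36	50	86	10	15	29	32
Thyroid	58	41	99	16	46	32	5
Melanoma	18	47	65	24	26	14	1
Colorectal	82	127	209	20	81	90	18
Kidney	16	39	55	8	25	17	6
NHL	19	28	47	13	15	9	10
Pancreatic	19	40	59	9	25	17	8
Liver and bile	35	78	113	36	33	32	12
Gastric	62	132	194	38	90	57	9
Head and neck	154	397	551	80	262	147	61
Esophageal	67	76	143	26	61	42	14
Bladder	10	22	32	4	12	14	2
Brain and CNS	8	34	42	11	13	14	4
Multiple myeloma	3	15	18	0	7	7	4
Gall bladder	18	17	35	3	18	13	1
Sarcoma	22	23	45	6	10	23	6
Prostate	0	122	122	17	37	55	13
Testicular	0	4	4	0	2	2	0
Vulvar	5	0	5	0	1	2	2
Anal	6	3	9	2	3	3	1
Vaginal	2	0	2	0	0	2	0
Penile	0	18	18	4	7	7	0
Unknown primary origin	4	2	6	NA	NA	NA	NA
Germ cell tumor	2	12	14	0	10	3	1
Squamous cell carcinoma	4	4	8	3	1	3	1
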