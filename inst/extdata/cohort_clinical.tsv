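case_id	sex	age	stage	smoking	histology	cfdna_ng_ml
case001	male	72	IV	current	LUSC	27.6
case002	male	67	IV	current	LUSC	42.7
case003	male	71	IV	current	LUSC	56.3
case004	male	75	IV	current	NSCLC_NOS	7.1
case005	male	81	IV	current	LUAD	15
case006	male	64	IV	current	LUSC	45.7
case007	male	80	IV	current	LUSC	11.3
case008	male	73	IV	current	NSCLC_NOS	15.8
case009	male	78	IV	current	LUAD	15.4
case010	male	77	IV	current	LUSC	8.2
case011	male	76	IV	current	LUAD	11.6
case012	male	62	IV	current	NSCLC_NOS	16.1
case013	male	69	IV	current	LUSC	11.8
case014	male	75	IV	current	NSCLC_NOS	42.4
case015	male	62	IV	ex	NSCLC_NOS	11.2
case016	male	66	III	ex	NSCLC_NOS	11.7
case017	male	75	II	ex	LUAD	29.6
case018	male	76	III	ex	NSCLC_NOS	7.3
case019	male	74	IV	ex	LUSC	16
case020	male	63	III	ex	LUSC	5.2
case021	male	61	IV	ex	LUSC	44.4
case022	male	82	IV	ex	LUAD	13.2
case023	male	72	III	ex	LUSC	11.3
case024	male	71	III	ex	LUSC	6.4
case025	male	69	IV	ex	LUSC	16.4
case026	male	60	IV	ex	LUSC	8.8
case027	male	75	IV	ex	NSCLC_NOS	10.8
case028	male	68	IV	ex	LUAD	49.3
case029	male	69	IV	ex	LUSC	14.3
case030	male	77	IV	ex	NSCLC_NOS	7.2
case031	male	77	III	ex	NSCLC_NOS	18.9
case032	male	81	IV	ex	LUAD	12.3
case033	male	66	IV	ex	LUSC	27
case034	male	75	IV	ex	LUSC	55.9
case035	male	81	IV	ex	NSCLC_NOS	7.6
case036	male	61	III	ex	LUAD	24.1
case037	male	63	IV	ex	NSCLC_NOS	17.7
case038	male	61	IV	ex	NSCLC_NOS	35.1
case039	male	58	III	ex	LUAD	13.7
case040	male	71	III	ex	LUSC	33.3
case041	male	75	IV	ex	LUAD	4.6
case042	male	80	IV	ex	NSCLC_NOS	70.1
case043	male	78	IV	ex	LUAD	34.2
case044	male	62	IV	ex	NSCLC_NOS	14.6
case045	male	85	IV	ex	LUSC	5.6
case046	male	65	III	ex	NSCLC_NOS	28.3
case047	male	71	IV	current	LUAD	24.7
case048	male	67	IV	current	LUSC	16.4
case049	male	69	I	current	LUAD	18.7
case050	male	72	III	current	NSCLC_NOS	10.4
case051	male	71	III	current	LUAD	22.4
case052	male	70	IV	current	LUAD	21.1
case053	male	71	IV	current	NSCLC_NOS	13.2
case054	female	66	III	current	LUSC	6
case055	female	66	III	current	LUAD	29.7
case056	female	57	III	current	LUAD	26.2
case057	female	67	IV	current	LUAD	8.6
case058	female	66	IV	current	NSCLC_NOS	5.1
case059	female	92	IV	current	LUAD	19.5
case060	female	59	I	current	NSCLC_NOS	12.5
case061	female	71	I	current	NSCLC_NOS	20.3
case062	female	58	III	NA	LUSC	6.2
case063	female	58	III	never	NSCLC_NOS	7.8
case064	female	71	IV	never	LUSC	41.4
case065	female	62	IV	never	LUAD	23.1
case066	female	70	III	never	LUAD	26.9
case067	female	67	III	never	LUAD	78.3
case068	female	65	III	never	LUSC	18.3
case069	female	54	IV	never	LUAD	4
case070	female	60	IV	never	LUSC	21.8
case071	female	71	IV	never	LUSC	44.5
case072	female	75	IV	never	LUAD	97.2
case073	female	66	IV	never	LUAD	5.8
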