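nodule_id	patient_id	bethesda	size_cm	histology	resected	alterations	rna_call	gc_call
N0001	P0001	III	1.9	hyperplasia	TRUE	NRAS	positive	positive
N0002	P0002	IV	1	hyperplasia	TRUE	HRAS	positive	positive
N0003	P0003	III	2.4	hyperplasia	TRUE		positive	positive
N0004	P0004	III	1.5	hyperplasia	TRUE		positive	positive
N0005	P0005	IV	0.6	hyperplasia	TRUE		positive	positive
N0006	P0006	III	2	hyperplasia	TRUE		positive	positive
N0007	P0007	IV	1.1	hyperplasia	TRUE		positive	negative
N0008	P0008	III	2.5	hyperplasia	TRUE		negative	negative
N0009	P0009	III	1.6	hyperplasia	TRUE		negative	negative
N0010	P0010	IV	0.7	hyperplasia	TRUE		negative	negative
N0011	P0011	III	2.1	hyperplasia	TRUE		negative	negative
N0012	P0012	III	1.2	hyperplasia	TRUE		negative	negative
N0013	P0013	IV	2.6	thyroiditis	TRUE		positive	positive
N0014	P0014	III	1.7	thyroiditis	TRUE		positive	positive
N0015	P0015	IV	0.8	adenoma	TRUE		negative	negative
N0016	P0016	III	2.2	NIFTP	TRUE	BRAF:K601E	positive	positive
N0017	P0017	III	1.3	NIFTP	TRUE	NRAS	positive	positive
N0018	P0018	IV	2.7	NIFTP	TRUE	NRAS	positive	positive
N0019	P0019	III	1.8	WT_UMP	TRUE	BRAF:K601E	positive	positive
N0020	P0020	III	0.9	WT_UMP	TRUE	NRAS	positive	positive
N0021	P0021	IV	2.3	WT_UMP	TRUE		positive	positive
N0022	P0022	III	1.4	WT_UMP	TRUE		positive	negative
N0023	P0023	IV	0.5	WT_UMP	TRUE		positive	negative
N0024	P0024	III	1.9	WT_UMP	TRUE		negative	negative
N0025	P0025	III	1	WT_UMP	TRUE		negative	negative
N0026	P0026	IV	2.4	PTC_classic	TRUE	BRAF:V600E	positive	positive
N0027	P0027	III	1.5	PTC_classic	TRUE	BRAF:V600E	positive	positive
N0028	P0028	III	0.6	PTC_classic	TRUE	BRAF:V600E	positive	positive
N0029	P0029	IV	2	PTC_classic	TRUE	KRAS	positive	positive
N0030	P0030	III	1.1	PTC_classic	TRUE	NRAS	positive	positive
N0031	P0031	IV	2.5	PTC_classic	TRUE	ETV6-NTRK3:fusion	positive	positive
N0032	P0032	III	1.6	PTC_classic	TRUE	ETV6-NTRK3:fusion	positive	positive
N0033	P0033	III	0.7	PTC_classic	TRUE		positive	positive
N0034	P0034	IV	2.1	PTC_classic	TRUE		positive	positive
N0035	P0035	III	1.2	PTC_classic_follicular	TRUE	ETV6-NTRK3:fusion	positive	positive
N0036	P0036	III	2.6	PTC_classic_follicular	TRUE		positive	positive
N0037	P0037	IV	1.7	PTC_classic_follicular	TRUE		positive	negative
N0038	P0038	III	0.8	PTC_follicular	TRUE	BRAF:V600E	positive	positive
N0039	P0039	IV	2.2	PTC_follicular	TRUE	NRAS	positive	positive
N0040	P0040	III	1.3	PTC_follicular	TRUE	NRAS	positive	positive
N0041	P0041	III	2.7	PTC_follicular	TRUE	CCDC6-RET:fusion	positive	positive
N0042	P0042	IV	1.8	PTC_follicular	TRUE	ETV6-NTRK3:fusion	positive	positive
N0043	P0043	III	0.9	PTC_follicular	TRUE	NCOA4-RET:fusion	positive	positive
N0044	P0044	III	2.3	PTC_follicular	TRUE	STRN-ALK:fusion	positive	positive
N0045	P0045	IV	1.4	PTC_follicular	TRUE		positive	positive
N0046	P0046	III	0.5	PTC_follicular	TRUE		positive	positive
N0047	P0047	IV	1.9	PTC_follicular	TRUE		positive	positive
N0048	P0048	III	1	PTC_follicular	TRUE		positive	positive
N0049	P0049	III	2.4	PTC_follicular	TRUE		positive	positive
N0050	P0050	IV	1.5	PTC_follicular	TRUE		positive	positive
N0051	P0051	III	0.6	PTC_follicular	TRUE		positive	positive
N0052	P0052	III	2	PTC_follicular	TRUE		positive	positive
N0053	P0053	IV	1.1	PTC_solid	TRUE		positive	positive
N0054	P0054	III	2.5	PTC_oncocytic	TRUE	KRAS	positive	positive
N0055	P0055	IV	1.6	follicular_carcinoma	TRUE		positive	positive
N0056	P0056	III	0.7	hurthle_carcinoma	TRUE		positive	positive
N0057	P0057	III	2.1	hurthle_carcinoma	TRUE	TERT	negative	positive
N0058	P0058	IV	1.2	anaplastic_carcinoma	TRUE	TERT;BRAF:V600E	positive	positive
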