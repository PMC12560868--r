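iid	status	family	sire
BULL_001	purebred	FAM_01	NA
BULL_002	purebred	FAM_02	NA
BULL_003	purebred	FAM_03	NA
BULL_004	purebred	NA	NA
COW_001	purebred	FAM_01	BULL_001
COW_002	purebred	FAM_02	BULL_002
COW_003	purebred	FAM_03	BULL_003
COW_004	purebred	FAM_01	BULL_001
COW_005	purebred	FAM_03	BULL_003
COW_006	purebred	FAM_01	BULL_001
COW_007	purebred	FAM_01	BULL_001
COW_008	purebred	FAM_02	BULL_002
COW_009	purebred	FAM_02	BULL_002
COW_010	purebred	FAM_02	BULL_002
COW_011	purebred	FAM_03	BULL_003
COW_012	purebred	FAM_01	BULL_001
COW_013	admixed	NA	NA
COW_014	admixed	NA	NA
COW_015	admixed	NA	NA
COW_016	admixed	NA	NA
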