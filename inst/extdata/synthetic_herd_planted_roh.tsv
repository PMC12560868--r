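iid	chrom	start_bp	end_bp
BULL_001	4	1327266	16561454
BULL_003	5	5252165	9265917
COW_003	1	2780084	13181933
COW_005	3	5728994	12262164
COW_007	4	13446172	17447302
COW_007	4	3522974	11768144
COW_008	5	2730362	17475496
COW_009	3	517098	9292634
COW_010	5	4093601	10041164
COW_011	2	3834045	15736691
COW_015	3	41959	10578305
COW_015	1	12637128	16960769
COW_016	5	9592700	15416960
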