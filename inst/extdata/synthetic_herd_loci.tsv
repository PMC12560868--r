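marker_id	role
SNP4_2	panel
SNP3_21	panel
SNP4_9	panel
SNP1_7	panel
SNP4_8	panel
SNP3_22	panel
SNP2_13	panel
SNP3_19	panel
SNP2_16	panel
SNP3_5	panel
SNP3_8	panel
SNP1_18	panel
SNP5_17	hwe_violator
SNP2_24	hwe_violator
SNP4_22	hwe_violator
SNP2_15	rare
SNP5_5	rare
SNP2_14	rare
SNP3_11	rare
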