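lesion_id,category,station_or_organ,count
M_fn_1,M,contralateral_lung,11
M_fn_2,M,liver,6
M_fn_3,M,brain,4
M_fn_4,M,adrenal_gland,3
M_fn_5,M,distant_lymph_node,2
M_fn_6,M,peritoneum,1
M_fn_7,M,bone,1
M_fn_8,M,pleura,1
M_fn_9,M,kidney,1
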