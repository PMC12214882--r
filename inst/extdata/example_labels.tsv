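sample_id	label
HRD_001	HRD
HRD_002	HRD
HRD_003	HRD
HRD_004	HRD
HRP_001	HRP
HRP_002	HRP
HRP_003	HRP
HRP_004	HRP
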