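quantity	numerator	denominator	digits
projected	835	889	1
excluded_out_of_range	54	889	1
lod_below_3	127	889	1
lod_3_to_6	575	889	1
minor_effect_r2_below_10	613	889	2
gwas_validated_mqtls	45	67	1
tier_high	44	802	2
tier_medium	566	802	2
tier_low	192	802	2
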