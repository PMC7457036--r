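swine	sum_q_lad	sum_q_lcx	lv_edv	peak_lvp
1	18.09	9.38	50.95	107.31
2	11.62	8.27	44.18	114.12
3	18.61	14.54	53.83	107.21
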