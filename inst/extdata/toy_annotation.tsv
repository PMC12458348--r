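transcript_id	cds_start	cds_end
t1	10	40
t2	0	21
t3	30	66
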