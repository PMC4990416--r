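gene,transcript_start,transcript_end,intron_length_after
synthetic_ACTB_construct,0,133,306
synthetic_ACTB_construct,133,269,NA
synthetic_HPRT1_construct,0,111,876
synthetic_HPRT1_construct,111,216,NA
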